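# End-to-end orchestration: derived scores -> adjusted regressions ->
# microbiota constructs -> block screening -> the structural models
# (topologies x constructs), returning report tables shaped like the
# analysis outputs (adjusted contrasts, diversity regressions, taxon
# screen, block eligibility, per-model parameters / fit / effects).

#' Pipeline configuration
#'
#' @param generator a [generator_config()] for simulation mode, or NULL.
#' @param cohort_path,counts_path,taxonomy_path input files (ignored in
#'   simulation mode).
#' @param topologies subset of
#'   \code{c("simplest","simple","complex","complex_path")}.
#' @param constructs subset of
#'   \code{c("shannon","streptococcaceae","pcoa1","cluster")}.
#' @param threshold latent-construct eligibility cut-off.
#' @param output_dir optional directory to write CSV/JSON artifacts into.
#' @param seed seed for simulation mode (overrides the generator's).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(generator = NULL, cohort_path = NULL,
                            counts_path = NULL, taxonomy_path = NULL,
                            topologies = c("simplest", "simple", "complex",
                                           "complex_path"),
                            constructs = c("shannon", "streptococcaceae",
                                           "pcoa1", "cluster"),
                            threshold = 0.2, output_dir = NULL,
                            seed = NULL) {
  topologies <- match.arg(topologies, several.ok = TRUE)
  constructs <- match.arg(constructs, several.ok = TRUE)
  if (!length(topologies) || !length(constructs))
    stop("select at least one topology and one construct", call. = FALSE)
  if (is.null(generator) &&
      (is.null(cohort_path) || is.null(counts_path) || is.null(taxonomy_path)))
    stop("either a generator config or all three input paths are required",
         call. = FALSE)
  if (!is.null(generator) && !is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, cohort_path = cohort_path,
                 counts_path = counts_path, taxonomy_path = taxonomy_path,
                 topologies = topologies, constructs = constructs,
                 threshold = threshold, output_dir = output_dir),
            class = "pipeline_config")
}

# numeric recodes the structural models expect
prepare_model_data <- function(cohort, constructs) {
  d <- merge(cohort, constructs, by.x = "child_id", by.y = "sample_id")
  d$aat <- as.integer(d$aat_class == "elevated")
  d$birth_size <- match(d$birth_size, c("smaller", "same", "bigger"))
  d$cluster <- as.numeric(d$cluster)
  d
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return a report bundle (list): \code{cohort_summary},
#'   \code{adjusted_contrasts}, \code{diversity_regressions},
#'   \code{taxon_screen}, \code{block_eligibility}, \code{constructs},
#'   \code{models} (per topology x construct: fit, statistics, standardized
#'   estimates, effect decompositions), \code{effect_table}, \code{log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$generator)) {
    gen <- .stage("simulate", {
      g <- generate_cohort(config$generator)
      tc <- generate_taxa_counts(config$generator, g$truth)
      list(cohort = g$cohort, truth = g$truth, counts = tc$counts,
           taxonomy = tc$taxonomy, run_label = tc$run_label)
    })
  } else {
    gen <- .stage("read-inputs", list(
      cohort = read_cohort(config$cohort_path),
      truth = NULL,
      counts = read_counts(config$counts_path),
      taxonomy = read_taxonomy(config$taxonomy_path),
      run_label = NULL))
  }
  cohort <- gen$cohort

  summary_tab <- .stage("cohort-summary", cohort_summary(cohort))

  adj_cov <- c("ses_score_cat", "running_water", "sex", "age", "anemia",
               "mother_age_first_preg", "mother_edu")
  contrasts <- .stage("adjusted-contrasts", {
    outs <- c("overall_score", "comm", "ps", "pes", "fm", "gm")
    do.call(rbind, lapply(outs, function(o) {
      ct <- adjusted_contrast(cohort, o, adj_cov)
      ct$outcome <- o
      ct
    }))
  })

  constructs_tab <- .stage("constructs",
                           build_constructs(gen$counts, gen$taxonomy))

  div_reg <- .stage("diversity-regressions", {
    div <- alpha_diversity(gen$counts)
    d <- merge(cohort, div, by.x = "child_id", by.y = "sample_id")
    run <- gen$run_label %||% rep("run1", nrow(gen$counts))
    run_d <- as.numeric(factor(run))[match(d$child_id, rownames(gen$counts))]
    do.call(rbind, lapply(c("richness", "shannon", "inverse_simpson"),
      function(ix) {
        X <- data.frame(index = d[[ix]], run = run_d)
        f <- ols_fit(d$overall_score, X)
        co <- f$coefficients[f$coefficients$term == "index", ]
        data.frame(index = ix, beta = co$estimate, p = co$p,
                   r_squared = f$r_squared, n = f$n,
                   stringsAsFactors = FALSE)
      }))
  })

  screen <- .stage("taxon-screen", {
    fam <- aggregate_taxa(gen$counts, gen$taxonomy, "family")
    fam_rel <- relative_abundance(fam)
    sc <- cohort[, c("comm", "ps", "pes", "fm", "gm", "overall_score")]
    rownames(sc) <- cohort$child_id
    screen_taxa(fam_rel, sc, level = "family")
  })

  blocks <- .stage("block-eligibility", {
    defs <- list(
      neurodevelopment = list(vars = c("comm", "ps", "pes", "fm", "gm"),
                              types = rep("continuous", 5)),
      ses_maternal = list(vars = c("ses_score_cat", "mother_edu",
                                   "mother_age_first_preg", "treated_water",
                                   "rooms"),
                          types = c("categorical", "categorical",
                                    "continuous", "categorical",
                                    "continuous")),
      bcaa = list(vars = c("alanine", "citrulline", "valine", "leucine",
                           "isoleucine"),
                  types = rep("continuous", 5)),
      parasites = list(vars = c("ascaris", "trichuris", "giardia",
                                "blastocystis", "enterobius", "hymenolepis"),
                       types = rep("categorical", 6)))
    lapply(defs, function(b)
      screen_block(cohort[, b$vars], b$types, threshold = config$threshold))
  })

  mdata <- .stage("model-data", prepare_model_data(cohort, constructs_tab))

  models <- list()
  for (mc in config$constructs) {
    catalog <- build_model_catalog(mc)
    for (tp in config$topologies) {
      entry <- catalog[[tp]]
      key <- paste(tp, mc, sep = ".")
      models[[key]] <- .stage(paste0("model-", key), {
        fit <- sem_estimate(entry$spec, mdata)
        neuro_node <- if (tp == "complex_path") "overall_score" else "neuro"
        ses_node <- if (tp == "complex_path") "rooms" else "ses"
        eff <- list(
          ses_neuro = sem_effects(fit, ses_node, neuro_node),
          micro_neuro = sem_effects(fit, mc, neuro_node))
        list(topology = tp, construct = mc, fit = fit,
             statistics = fit_statistics(fit),
             standardized = sem_standardize(fit),
             effects = eff, n = fit$n)
      })
    }
  }

  eff_tab <- render_effect_table(models)

  bundle <- list(cohort_summary = summary_tab,
                 adjusted_contrasts = contrasts,
                 diversity_regressions = div_reg,
                 taxon_screen = screen,
                 block_eligibility = blocks,
                 constructs = constructs_tab,
                 models = models,
                 effect_table = eff_tab,
                 truth = gen$truth,
                 log = list(seed = if (!is.null(config$generator))
                              config$generator$seed else NA_integer_,
                            package_version =
                              as.character(utils::packageVersion("stuntsem")),
                            n_children = nrow(cohort),
                            n_per_model = vapply(models, `[[`, integer(1), "n"),
                            timestamp_utc = format(Sys.time(), tz = "UTC")))
  if (!is.null(config$output_dir)) .write_bundle(bundle, config$output_dir)
  bundle
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$cohort_summary,
                   file.path(dir, "cohort_summary.csv"), row.names = FALSE)
  utils::write.csv(bundle$adjusted_contrasts,
                   file.path(dir, "adjusted_contrasts.csv"), row.names = FALSE)
  utils::write.csv(bundle$diversity_regressions,
                   file.path(dir, "diversity_regressions.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$taxon_screen, file.path(dir, "taxon_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$effect_table, file.path(dir, "effect_table.csv"),
                   row.names = FALSE)
  fitstats <- lapply(bundle$models, function(m)
    unclass(m$statistics))
  jsonlite::write_json(fitstats, file.path(dir, "fit_statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Long-format direct-effect table across fitted models
#'
#' One row per (model, predictor of the neurodevelopment node, effect
#' type), with 95% CI and a significance flag at 0.05.
#'
#' @param models the \code{models} element of a [run_pipeline()] bundle
#'   (possibly empty).
#' @return data frame: model, construct, predictor, effect, estimate,
#'   ci_lower, ci_upper, p, significant.
#' @export
render_effect_table <- function(models) {
  empty <- data.frame(model = character(), construct = character(),
                      predictor = character(), effect = character(),
                      estimate = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(models)) return(empty)
  rows <- lapply(models, function(m) {
    neuro_node <- if (m$topology == "complex_path") "overall_score" else "neuro"
    est <- m$fit$estimates
    direct <- est[est$kind == "path" &
                    startsWith(est$label, paste0(neuro_node, "~")), ]
    if (!nrow(direct)) return(NULL)
    data.frame(model = m$topology, construct = m$construct,
               predictor = sub(paste0("^", neuro_node, "~"), "", direct$label),
               effect = "direct", estimate = direct$estimate,
               ci_lower = direct$estimate - 1.96 * direct$se,
               ci_upper = direct$estimate + 1.96 * direct$se,
               p = direct$p, significant = direct$p <= 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
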