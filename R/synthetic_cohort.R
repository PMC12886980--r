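# Synthetic cohort + taxa-count generator with stored ground truth.
#
# The generative model mirrors the structural assumptions of the analysis:
# standard-normal latent SES and BCAA factors; hemoglobin driven by its own
# latent deviate; HAZ a linear combination of SES, hemoglobin and BCAA plus
# noise; a latent microbiota diversity driver fed by SES and BCAA; a latent
# neurodevelopment factor fed by SES, HAZ and the diversity driver; and
# observed indicators = loading x latent + noise, discretized to each
# indicator's declared scale.

# Edges the generator understands (directed, "source->target").
.known_edges <- c("SES->HAZ", "Hb->HAZ", "BCAA->HAZ", "Micro->HAZ",
                  "SES->Micro", "BCAA->Micro",
                  "SES->Neuro", "HAZ->Neuro", "Micro->Neuro",
                  "AAT->Neuro", "Age->Neuro", "BirthSize->Neuro")

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the package's models assume: a
#' cohort of 349 children aged 24--60 months with stunting-category mix
#' 56.4/24.1/19.5%, an amplicon table of 1626 taxa in 25 family blocks at a
#' mean library size of 22039 reads, and structural coefficients of modest,
#' epidemiologically plausible size (SES and HAZ effects on neurodevelopment
#' around 0.3 standard deviations, a small positive diversity effect, a
#' negative BCAA--diversity path).
#'
#' @param n_children number of children.
#' @param seed integer seed; fully determines all output.
#' @param category_probs probabilities of (normal, moderate, severe)
#'   stunting used by the \code{"category"} HAZ mode; must sum to 1.
#' @param loadings_neuro loadings of the five ASQ-3 domains (Comm, PS, PES,
#'   FM, GM) on latent neurodevelopment.
#' @param loadings_ses loadings of socioeconomic score, maternal education,
#'   maternal age at first pregnancy, treated water, rooms on latent SES.
#' @param loadings_bcaa loadings of alanine, citrulline, valine, leucine,
#'   isoleucine on latent BCAA.
#' @param path_coefficients named numeric vector over directed edges such as
#'   \code{"SES->HAZ"}; unknown edge names are an error. Unnamed edges
#'   default to the values below.
#' @param noise_sd named vector of residual standard deviations for
#'   \code{HAZ}, \code{Neuro}, \code{Micro} and \code{indicator} (shared by
#'   all indicators); all must be positive.
#' @param haz_mode \code{"continuous"} (HAZ from the linear model,
#'   categories derived) or \code{"category"} (categories sampled directly
#'   with \code{category_probs}, HAZ drawn within the category band).
#' @param missing_rate MCAR missingness proportion applied to analysis
#'   columns (0 disables).
#' @param n_taxa,n_families number of taxa and of family blocks
#'   (\code{n_families <= n_taxa}).
#' @param depth_mean mean library size (Poisson).
#' @param dirichlet_concentration total concentration of the per-sample
#'   Dirichlet composition.
#' @param family_decay geometric decay of baseline family weights; 1 gives
#'   a uniform family-level base.
#' @param taxon_decay geometric decay of baseline taxon weights within a
#'   family; 1 gives a uniform within-family base.
#' @param diversity_tilt strength with which a child's diversity driver
#'   flattens (positive driver) or sharpens the family composition.
#' @param strep_coupling optional direct coupling of the Streptococcaceae
#'   block to latent neurodevelopment (0 = off, the default).
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_children = 349L, seed = 1L,
                             category_probs = c(normal = 0.564,
                                                moderate = 0.241,
                                                severe = 0.195),
                             loadings_neuro = c(comm = 1, ps = 1.2,
                                                pes = 0.9, fm = 1.15,
                                                gm = 0.95),
                             loadings_ses = c(ses_score = 1,
                                              mother_edu = 0.9,
                                              mother_age_first_preg = 0.6,
                                              treated_water = 0.7,
                                              rooms = 0.8),
                             loadings_bcaa = c(alanine = 1,
                                               citrulline = 0.7,
                                               valine = 1.1, leucine = 1.05,
                                               isoleucine = 1),
                             path_coefficients = NULL,
                             noise_sd = c(HAZ = 1.1, Neuro = 0.8,
                                          Micro = 0.9, indicator = 0.6),
                             haz_mode = c("continuous", "category"),
                             missing_rate = 0,
                             n_taxa = 1626L, n_families = 25L,
                             depth_mean = 22039L,
                             dirichlet_concentration = 50,
                             family_decay = 0.7,
                             taxon_decay = 0.9,
                             diversity_tilt = 0.6,
                             strep_coupling = 0) {
  haz_mode <- match.arg(haz_mode)
  if (n_children < 1) stop("n_children must be positive", call. = FALSE)
  if (abs(sum(category_probs) - 1) > 1e-12)
    stop("category_probs must sum to 1", call. = FALSE)
  defaults <- c("SES->HAZ" = 0.30, "Hb->HAZ" = 0.25, "BCAA->HAZ" = 0.25,
                "Micro->HAZ" = 0, "SES->Micro" = 0.15,
                "BCAA->Micro" = -0.30, "SES->Neuro" = 0.35,
                "HAZ->Neuro" = 0.30, "Micro->Neuro" = 0.10,
                "AAT->Neuro" = 0, "Age->Neuro" = 0, "BirthSize->Neuro" = 0)
  if (!is.null(path_coefficients)) {
    bad <- setdiff(names(path_coefficients), .known_edges)
    if (length(bad))
      stop("unknown edge name(s) in path_coefficients: ",
           paste(bad, collapse = ", "), call. = FALSE)
    defaults[names(path_coefficients)] <- path_coefficients
  }
  full_noise <- c(HAZ = 1.1, Neuro = 0.8, Micro = 0.9, indicator = 0.6)
  full_noise[names(noise_sd)] <- noise_sd
  if (any(full_noise <= 0)) stop("all noise_sd must be > 0", call. = FALSE)
  if (n_families > n_taxa)
    stop("n_families must not exceed n_taxa", call. = FALSE)
  stopifnot(length(loadings_neuro) == 5, length(loadings_ses) == 5,
            length(loadings_bcaa) == 5, missing_rate >= 0, missing_rate < 1,
            depth_mean > 0, dirichlet_concentration > 0)
  structure(list(n_children = as.integer(n_children), seed = as.integer(seed),
                 category_probs = category_probs,
                 loadings_neuro = loadings_neuro,
                 loadings_ses = loadings_ses,
                 loadings_bcaa = loadings_bcaa,
                 path_coefficients = defaults, noise_sd = full_noise,
                 haz_mode = haz_mode, missing_rate = missing_rate,
                 n_taxa = as.integer(n_taxa),
                 n_families = as.integer(n_families),
                 depth_mean = as.integer(depth_mean),
                 dirichlet_concentration = dirichlet_concentration,
                 family_decay = family_decay,
                 taxon_decay = taxon_decay,
                 diversity_tilt = diversity_tilt,
                 strep_coupling = strep_coupling),
            class = "generator_config")
}

# snap a continuous value to the ASQ-3 grid: multiples of 5 in [0, 60]
.asq_grid <- function(x) pmin(60L, pmax(0L, as.integer(5 * round(x / 5))))

# cut a standard-ish normal deviate into ordered levels at given
# cumulative probabilities
.cut_ordinal <- function(x, probs) {
  cuts <- stats::qnorm(cumsum(probs)[-length(probs)], sd = stats::sd(x))
  findInterval(x - mean(x), cuts) + 1L
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config a [generator_config()].
#' @return list with \code{cohort} (data frame, one row per child) and
#'   \code{truth} (data frame of realized latent scores plus the coefficient
#'   mapping in \code{attr(truth, "path_coefficients")}).
#' @export
#' @examples
#' g <- generate_cohort(generator_config(n_children = 50, seed = 7))
#' head(g$cohort[, c("child_id", "haz", "stunting_category", "overall_score")])
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_children
  b <- config$path_coefficients
  ns <- config$noise_sd

  ses <- stats::rnorm(n)
  bcaa <- stats::rnorm(n)
  hb_z <- stats::rnorm(n)
  hb <- round(11.6 + 1.4 * hb_z, 1)

  micro <- b["SES->Micro"] * ses + b["BCAA->Micro"] * bcaa +
    stats::rnorm(n, sd = ns["Micro"])

  age <- sample(24:60, n, replace = TRUE)
  sex <- stats::rbinom(n, 1, 0.5)
  birth_size <- sample(c("smaller", "same", "bigger"), n, replace = TRUE,
                       prob = c(0.2, 0.6, 0.2))
  bs_num <- match(birth_size, c("smaller", "same", "bigger"))
  aat_value <- round(exp(stats::rnorm(n, mean = log(1.0), sd = 0.5)), 3)
  aat_class <- ifelse(aat_value < threshold_policy()$aat_dry,
                      "normal", "elevated")
  aat_bin <- as.integer(aat_class == "elevated")

  if (config$haz_mode == "continuous") {
    haz <- -1.7 + b["SES->HAZ"] * ses + b["Hb->HAZ"] * hb_z +
      b["BCAA->HAZ"] * bcaa + b["Micro->HAZ"] * micro +
      stats::rnorm(n, sd = ns["HAZ"])
    haz <- round(haz, 4)
    stunting <- categorize_haz(haz)
  } else {
    stunting <- factor(sample(c("normal", "moderate", "severe"), n,
                              replace = TRUE, prob = config$category_probs),
                       levels = c("normal", "moderate", "severe"))
    haz <- round(ifelse(stunting == "severe", stats::runif(n, -4.5, -3),
                 ifelse(stunting == "moderate", stats::runif(n, -2.99, -2),
                        stats::runif(n, -1.99, 2))), 4)
  }

  neuro <- b["SES->Neuro"] * ses + b["HAZ->Neuro"] * haz +
    b["Micro->Neuro"] * micro + b["AAT->Neuro"] * aat_bin +
    b["Age->Neuro"] * (age - 42) / 10 +
    b["BirthSize->Neuro"] * (bs_num - 2) +
    stats::rnorm(n, sd = ns["Neuro"])

  # ASQ-3 domains: latent projection scaled to the printed score range and
  # snapped to the 5-point grid
  sdi <- ns["indicator"]
  doms <- sapply(config$loadings_neuro, function(l)
    .asq_grid(45 + 7 * (l * neuro + stats::rnorm(n, sd = sdi))))
  colnames(doms) <- c("comm", "ps", "pes", "fm", "gm")

  ses_ind <- sapply(config$loadings_ses, function(l)
    l * ses + stats::rnorm(n, sd = sdi))
  ses_score_cat <- .cut_ordinal(ses_ind[, 1], c(0.4, 0.4, 0.2))
  mother_edu <- .cut_ordinal(ses_ind[, 2], c(0.25, 0.3, 0.25, 0.15, 0.05))
  mother_age_first_preg <- pmax(13L, pmin(45L,
    as.integer(round(19.5 + 3.5 * ses_ind[, 3]))))
  treated_water <- as.integer(ses_ind[, 4] > 0)
  rooms <- pmax(1L, as.integer(round(2.5 + 0.8 * ses_ind[, 5])))
  running_water <- as.integer(0.5 * ses + stats::rnorm(n, sd = sdi) > 0.6)

  bcaa_scale <- rbind(alanine = c(350, 60), citrulline = c(24, 6),
                      valine = c(220, 40), leucine = c(110, 25),
                      isoleucine = c(60, 15))
  bcaa_ind <- sapply(seq_along(config$loadings_bcaa), function(j) {
    l <- config$loadings_bcaa[j]
    pmax(0.5, round(bcaa_scale[j, 1] +
      bcaa_scale[j, 2] * (l * bcaa + stats::rnorm(n, sd = sdi)), 1))
  })
  colnames(bcaa_ind) <- rownames(bcaa_scale)

  ferritin <- round(exp(stats::rnorm(n, log(30), 0.6)), 1)
  crp <- round(exp(stats::rnorm(n, log(2), 1)), 2)
  parasites <- sapply(c(ascaris = 0.493, trichuris = 0.618, giardia = 0.224,
                        blastocystis = 0.30, enterobius = 0.05,
                        hymenolepis = 0.03),
                      function(p) stats::rbinom(n, 1, p))
  gene_count <- stats::rpois(n, 1.5)
  food_p <- c(grains = 0.95, pulses = 0.50, dairy = 0.35, flesh = 0.60,
              eggs = 0.25, vita_fruit_veg = 0.45, other_fruit_veg = 0.55)
  foods <- sapply(food_p, function(p) stats::rbinom(n, 1, p))
  colnames(foods) <- paste0("food_", names(food_p))
  dd <- dietary_diversity(foods)
  currently_breastfed <- stats::rbinom(n, 1, 0.083)
  excl_bf_6m <- stats::rbinom(n, 1, 0.665)
  age_solid_food <- pmax(2L, pmin(12L, as.integer(round(stats::rnorm(n, 5, 1.2)))))

  cohort <- data.frame(
    child_id = sprintf("child_%04d", seq_len(n)),
    age = age, sex = sex, haz = haz,
    stunting_category = stunting,
    doms, overall_score = as.integer(rowSums(doms)),
    ses_score_cat = ses_score_cat, mother_edu = mother_edu,
    mother_age_first_preg = mother_age_first_preg,
    treated_water = treated_water, rooms = rooms,
    running_water = running_water,
    hemoglobin = hb, anemia = as.integer(hb < 11),
    ferritin = ferritin, crp = crp,
    bcaa_ind,
    aat_value = aat_value, aat_class = aat_class,
    birth_size = birth_size,
    parasites, enteropathogen_gene_count = gene_count,
    foods, dds = dd$dds, ldd = as.integer(dd$ldd),
    currently_breastfed = currently_breastfed, excl_bf_6m = excl_bf_6m,
    age_solid_food = age_solid_food,
    stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    protect <- c("child_id", "stunting_category", "overall_score")
    cols <- setdiff(names(cohort), protect)
    for (cl in cols) {
      hit <- stats::runif(n) < config$missing_rate
      cohort[[cl]][hit] <- NA
    }
  }

  truth <- data.frame(child_id = cohort$child_id, ses = ses, bcaa = bcaa,
                      neuro = neuro, hb_z = hb_z, diversity_driver = micro,
                      stringsAsFactors = FALSE)
  attr(truth, "path_coefficients") <- b
  attr(truth, "config") <- config
  list(cohort = cohort, truth = truth)
}

# candidate gut bacterial family names; Streptococcaceae always present
.family_pool <- c("Streptococcaceae", "Lachnospiraceae", "Ruminococcaceae",
                  "Prevotellaceae", "Bacteroidaceae", "Bifidobacteriaceae",
                  "Enterobacteriaceae", "Veillonellaceae", "Clostridiaceae",
                  "Erysipelotrichaceae", "Rikenellaceae", "Acidaminococcaceae",
                  "Oscillospiraceae", "Eubacteriaceae", "Coriobacteriaceae",
                  "Tannerellaceae", "Akkermansiaceae", "Desulfovibrionaceae",
                  "Enterococcaceae", "Lactobacillaceae", "Peptostreptococcaceae",
                  "Sutterellaceae", "Fusobacteriaceae", "Christensenellaceae",
                  "Micrococcaceae")

#' Generate a samples x taxa count table coupled to a cohort's ground truth
#'
#' Per-sample compositions are Dirichlet draws whose family-block
#' log-concentrations are tilted by the child's diversity driver (a more
#' positive driver flattens the family profile, raising alpha diversity);
#' counts are multinomial at a Poisson-distributed library size.
#'
#' @param config a [generator_config()].
#' @param truth ground-truth table from [generate_cohort()] for the same
#'   config.
#' @return list with \code{counts} (integer matrix, samples x taxa, sample
#'   ids as rownames), \code{taxonomy} (data frame taxon/family/genus) and
#'   \code{run_label} (per-sample sequencing batch).
#' @export
generate_taxa_counts <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_taxa < config$n_families)
    stop("n_taxa must be at least n_families", call. = FALSE)
  if (nrow(truth) != config$n_children)
    stop("truth does not match the configured number of children",
         call. = FALSE)
  set.seed(config$seed + 131071L)
  nf <- config$n_families
  nt <- config$n_taxa
  fams <- c(.family_pool, sprintf("Family%02d", seq_len(max(0, nf - length(.family_pool)))))[seq_len(nf)]
  base_w <- config$family_decay^(seq_len(nf) - 1)
  base_w <- base_w / sum(base_w)
  # allot taxa to families proportionally to base weight, >= 1 each
  sizes <- pmax(1L, as.integer(floor(base_w * nt)))
  while (sum(sizes) < nt) {
    j <- which.max(base_w * nt - sizes)
    sizes[j] <- sizes[j] + 1L
  }
  while (sum(sizes) > nt) {
    j <- which.max(ifelse(sizes > 1L, sizes - base_w * nt, -Inf))
    sizes[j] <- sizes[j] - 1L
  }
  fam_of_taxon <- rep(fams, sizes)
  # taxon-level base profile: geometric across families and within family
  within_rank <- unlist(lapply(sizes, function(m) seq_len(m) - 1L))
  q_base <- rep(base_w / sizes, sizes) * config$taxon_decay^within_rank
  q_base <- q_base / sum(q_base)
  taxonomy <- data.frame(
    taxon = sprintf("ASV%04d", seq_len(nt)),
    family = fam_of_taxon,
    genus = ifelse(fam_of_taxon == "Streptococcaceae", "Streptococcus",
                   paste0(sub("aceae$", "", fam_of_taxon), "_g",
                          unlist(lapply(sizes, function(s)
                            rep_len(1:3, s))))),
    stringsAsFactors = FALSE)

  n <- nrow(truth)
  driver <- truth$diversity_driver
  counts <- matrix(0L, n, nt,
                   dimnames = list(truth$child_id, taxonomy$taxon))
  depth <- stats::rpois(n, config$depth_mean)
  strep_taxa <- fam_of_taxon == "Streptococcaceae"
  for (i in seq_len(n)) {
    # a positive driver flattens the whole log-concentration profile,
    # raising evenness and hence alpha diversity
    tilt <- exp(config$diversity_tilt * driver[i])
    w <- q_base^(1 / tilt)
    if (config$strep_coupling != 0)
      w[strep_taxa] <- w[strep_taxa] *
        exp(-config$strep_coupling * truth$neuro[i])
    w <- w / sum(w)
    alpha <- config$dirichlet_concentration * w
    g <- stats::rgamma(nt, shape = alpha, rate = 1)
    p <- g / sum(g)
    counts[i, ] <- as.integer(stats::rmultinom(1, depth[i], p))
  }
  list(counts = counts, taxonomy = taxonomy,
       run_label = rep(c("run1", "run2"), length.out = n))
}
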