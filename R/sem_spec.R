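# Model specification and RAM construction for the covariance-structure
# engine.  A model is a measurement part (latent =~ indicators, first
# loading fixed to 1 for scaling) plus a structural part (directed paths
# among latent and/or observed variables).  The RAM form collects directed
# edges in A, (co)variances in Omega, and selects observed rows with F, so
# the model-implied covariance is F (I-A)^-1 Omega (I-A)^-T F'.

#' Specify a structural equation model
#'
#' @param measurement named list: latent variable -> character vector of
#'   indicator variables.  The FIRST indicator's loading is fixed to 1 to
#'   scale the latent; the rest are free.  May be empty (path analysis).
#' @param structural named list: outcome -> character vector of predictors
#'   (latent or observed).  The directed graph must be acyclic.
#' @param covariances optional list of length-2 character vectors naming
#'   free covariance pairs.  Default \code{NULL}: all exogenous variables
#'   (no incoming edge) covary freely, the standard convention.
#'   \code{FALSE} forces orthogonal exogenous variables.
#' @return object of class \code{sem_spec}.
#' @export
#' @examples
#' sem_spec(measurement = list(f = c("y1", "y2", "y3", "y4")))
sem_spec <- function(measurement = list(), structural = list(),
                     covariances = NULL) {
  stopifnot(is.list(measurement), is.list(structural))
  latent <- names(measurement)
  if (length(measurement) && (is.null(latent) || any(latent == "")))
    stop("measurement list must be named by latent variable", call. = FALSE)
  for (l in latent) {
    if (length(measurement[[l]]) < 1)
      stop("latent '", l, "' needs at least one indicator", call. = FALSE)
    if (anyDuplicated(measurement[[l]]))
      stop("duplicate indicator for latent '", l, "'", call. = FALSE)
  }
  indicators <- unlist(measurement, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("an indicator may load on only one latent here: ",
         paste(unique(indicators[duplicated(indicators)]), collapse = ", "),
         call. = FALSE)
  if (any(latent %in% indicators))
    stop("a latent variable cannot be its own indicator", call. = FALSE)

  edges <- list()
  for (out in names(structural)) {
    preds <- structural[[out]]
    if (anyDuplicated(preds))
      stop("duplicate edge into '", out, "'", call. = FALSE)
    if (out %in% preds)
      stop("self-loop on '", out, "'", call. = FALSE)
    edges[[out]] <- preds
  }
  # acyclicity by repeated removal of sink-free nodes (Kahn)
  nodes <- unique(c(names(edges), unlist(edges), latent, indicators))
  incoming <- edges
  remaining <- nodes
  repeat {
    sinks <- remaining[!vapply(remaining, function(v)
      length(intersect(incoming[[v]], remaining)) > 0, logical(1))]
    if (!length(sinks)) break
    remaining <- setdiff(remaining, sinks)
  }
  if (length(remaining))
    stop("structural graph is cyclic (involves: ",
         paste(remaining, collapse = ", "), ")", call. = FALSE)

  observed <- setdiff(nodes, latent)
  structure(list(measurement = measurement, structural = structural,
                 covariances = covariances,
                 latent = latent, observed = observed),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("SEM specification:", length(x$latent), "latent,",
      length(x$observed), "observed variables\n")
  for (l in x$latent)
    cat("  ", l, "=~", paste(x$measurement[[l]], collapse = " + "), "\n")
  for (o in names(x$structural))
    cat("  ", o, "~", paste(x$structural[[o]], collapse = " + "), "\n")
  invisible(x)
}

# variables with no incoming directed edge (neither indicator nor outcome)
.exogenous_vars <- function(spec) {
  endo <- unique(c(unlist(spec$measurement, use.names = FALSE),
                   names(spec$structural)))
  setdiff(c(spec$observed, spec$latent), endo)
}

#' Build the RAM representation of a model specification
#'
#' Maps every free parameter to exactly one cell of A (directed edges) or
#' one symmetric cell pair of Omega (variances/covariances); fixed-to-1
#' loadings are written as constants.
#'
#' @param spec a [sem_spec()].
#' @return object of class \code{sem_ram}: variable order (observed first),
#'   selection matrix \code{F}, fixed part \code{A_fixed}, and a parameter
#'   table with one row per free parameter (label, target matrix, indices,
#'   kind).
#' @export
build_ram <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  vars <- c(spec$observed, spec$latent)
  nv <- length(vars)
  idx <- stats::setNames(seq_len(nv), vars)
  A_fixed <- matrix(0, nv, nv, dimnames = list(vars, vars))
  params <- list()
  add <- function(label, mat, i, j, kind, scale_var = NA_character_) {
    params[[length(params) + 1]] <<-
      data.frame(label = label, mat = mat, i = i, j = j, kind = kind,
                 scale_var = scale_var, stringsAsFactors = FALSE)
  }
  for (l in spec$latent) {
    ind <- spec$measurement[[l]]
    A_fixed[idx[ind[1]], idx[l]] <- 1          # scaling indicator
    for (v in ind[-1])
      add(paste0(l, "=~", v), "A", idx[v], idx[l], "loading")
  }
  for (out in names(spec$structural)) for (pr in spec$structural[[out]]) {
    if (A_fixed[idx[out], idx[pr]] != 0)
      stop("duplicate edge ", pr, " -> ", out, call. = FALSE)
    add(paste0(out, "~", pr), "A", idx[out], idx[pr], "path")
  }
  # variances: every variable gets a free (residual) variance
  scale_ind <- stats::setNames(
    vapply(spec$latent, function(l) spec$measurement[[l]][1], character(1)),
    spec$latent)
  for (v in vars) {
    sv <- if (v %in% spec$latent) scale_ind[[v]] else v
    add(paste0("var(", v, ")"), "Omega", idx[v], idx[v], "variance", sv)
  }
  # free covariances among exogenous variables (or the explicit list)
  cov_pairs <- if (is.null(spec$covariances)) {
    exo <- .exogenous_vars(spec)
    if (length(exo) >= 2) utils::combn(sort(exo), 2, simplify = FALSE)
    else list()
  } else if (identical(spec$covariances, FALSE)) list()
  else spec$covariances
  for (pr in cov_pairs) {
    add(paste0("cov(", pr[1], ",", pr[2], ")"), "Omega",
        idx[pr[1]], idx[pr[2]], "covariance",
        if (pr[1] %in% spec$latent) scale_ind[[pr[1]]] else pr[1])
  }
  params <- do.call(rbind, params)
  if (anyDuplicated(params$label))
    stop("duplicate parameter labels", call. = FALSE)
  Fmat <- matrix(0, length(spec$observed), nv,
                 dimnames = list(spec$observed, vars))
  Fmat[cbind(seq_along(spec$observed), idx[spec$observed])] <- 1
  structure(list(spec = spec, vars = vars, observed = spec$observed,
                 latent = spec$latent, F = Fmat, A_fixed = A_fixed,
                 params = params, n_free = nrow(params)),
            class = "sem_ram")
}

# assemble A and Omega for a parameter vector theta (order = ram$params)
.ram_matrices <- function(ram, theta) {
  A <- ram$A_fixed
  nv <- length(ram$vars)
  Omega <- matrix(0, nv, nv, dimnames = dimnames(A))
  pt <- ram$params
  for (r in seq_len(nrow(pt))) {
    if (pt$mat[r] == "A") {
      A[pt$i[r], pt$j[r]] <- theta[r]
    } else {
      Omega[pt$i[r], pt$j[r]] <- theta[r]
      Omega[pt$j[r], pt$i[r]] <- theta[r]
    }
  }
  list(A = A, Omega = Omega)
}

#' Model-implied covariance matrix
#'
#' @param ram a [build_ram()] object.
#' @param theta numeric vector of free parameters in the order of
#'   \code{ram$params} (names are checked if present).
#' @return the implied covariance of the observed variables.
#' @export
implied_sigma <- function(ram, theta) {
  stopifnot(inherits(ram, "sem_ram"), length(theta) == ram$n_free)
  if (!is.null(names(theta)) &&
      !identical(unname(names(theta)), unname(ram$params$label)))
    theta <- theta[ram$params$label]
  m <- .ram_matrices(ram, theta)
  IA <- diag(length(ram$vars)) - m$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("(I - A) is singular", call. = FALSE))
  S <- ram$F %*% B %*% m$Omega %*% t(B) %*% t(ram$F)
  (S + t(S)) / 2
}

# ---- plain-text model-spec files -------------------------------------------
# Three sections: 'measurement:' (latent =~ i1 + i2 + ...), 'structural:'
# (outcome ~ p1 + p2 + ...), 'variances:' (a ~~ b free-covariance pairs;
# 'none' = orthogonal exogenous).  '#' starts a comment.

#' Read / write a model-spec file
#'
#' @param path file path.
#' @return \code{read_sem_spec} returns a [sem_spec()];
#'   \code{write_sem_spec} returns \code{path} invisibly.  The two
#'   round-trip.
#' @export
read_sem_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  measurement <- list(); structural <- list(); cov <- NULL
  for (ln in lines) {
    if (grepl("^(measurement|structural|variances):$", ln)) {
      section <- sub(":$", "", ln)
      next
    }
    if (is.na(section)) stop("line outside any section: ", ln, call. = FALSE)
    if (section == "measurement") {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("bad measurement line: ", ln, call. = FALSE)
      measurement[[trimws(parts[1])]] <-
        trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    } else if (section == "structural") {
      parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("bad structural line: ", ln, call. = FALSE)
      structural[[trimws(parts[1])]] <-
        trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    } else {
      if (identical(ln, "none")) { cov <- FALSE; next }
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      if (length(parts) != 2) stop("bad variances line: ", ln, call. = FALSE)
      if (is.null(cov) || identical(cov, FALSE)) cov <- list()
      cov[[length(cov) + 1]] <- parts
    }
  }
  sem_spec(measurement, structural, cov)
}

#' @rdname read_sem_spec
#' @param spec a [sem_spec()].
#' @export
write_sem_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sem_spec"))
  out <- character()
  if (length(spec$measurement)) {
    out <- c(out, "measurement:")
    for (l in names(spec$measurement))
      out <- c(out, paste0("  ", l, " =~ ",
                           paste(spec$measurement[[l]], collapse = " + ")))
  }
  if (length(spec$structural)) {
    out <- c(out, "structural:")
    for (o in names(spec$structural))
      out <- c(out, paste0("  ", o, " ~ ",
                           paste(spec$structural[[o]], collapse = " + ")))
  }
  if (!is.null(spec$covariances)) {
    out <- c(out, "variances:")
    if (identical(spec$covariances, FALSE)) {
      out <- c(out, "  none")
    } else {
      for (pr in spec$covariances)
        out <- c(out, paste0("  ", pr[1], " ~~ ", pr[2]))
    }
  }
  writeLines(out, path)
  invisible(path)
}
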