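# Classification and composite-score rules for anthropometry, diet and
# biomarkers.  All cut-offs live in one ThresholdPolicy object so boundary
# conventions (inclusive vs strict) are stated once and tested once.

#' Threshold policy for derived scores
#'
#' Bundles every clinical cut-off used by the score and classification
#' helpers.  Defaults follow standard WHO / field conventions: stunting at
#' HAZ <= -2, severe stunting at HAZ <= -3, anemia below 11 g/dL (altitude-
#' adjusted hemoglobin), low ferritin below 12 ug/L after multiplying by
#' 0.67 when CRP exceeds 6 mg/L, elevated CRP above 10 mg/L, citrulline low
#' below 7 umol/L and elevated above 43 umol/L, virulence-gene presence at
#' qPCR Ct < 37, fecal alpha-1-antitrypsin normal below 1.25 mg/g dry weight
#' (0.15 wet weight), and low dietary diversity strictly below 4 of 7 food
#' groups.
#'
#' @param haz_stunted HAZ at or below which a child is (at least) moderately
#'   stunted.
#' @param haz_severe HAZ at or below which a child is severely stunted.
#' @param anemia_hb hemoglobin (g/dL) below which anemia is diagnosed.
#' @param ferritin_low corrected ferritin (ug/L) below which iron stores are
#'   low.
#' @param crp_correction CRP (mg/L) above which ferritin is multiplied by
#'   \code{ferritin_factor}.
#' @param crp_elevated CRP (mg/L) above which inflammation is flagged.
#' @param ferritin_factor multiplicative inflammation correction for
#'   ferritin.
#' @param citrulline_low,citrulline_high citrulline class bounds (umol/L).
#' @param ct_presence qPCR cycle threshold strictly below which a gene is
#'   present.
#' @param aat_dry,aat_wet alpha-1-antitrypsin normal/elevated cut-offs on
#'   the dry-weight (mg/g) and wet-weight bases.
#' @param ldd_cut dietary diversity score strictly below which diversity is
#'   low.
#' @return an object of class \code{threshold_policy}.
#' @export
#' @examples
#' p <- threshold_policy()
#' categorize_haz(c(0, -2, -3), p)
threshold_policy <- function(haz_stunted = -2, haz_severe = -3,
                             anemia_hb = 11, ferritin_low = 12,
                             crp_correction = 6, crp_elevated = 10,
                             ferritin_factor = 0.67,
                             citrulline_low = 7, citrulline_high = 43,
                             ct_presence = 37,
                             aat_dry = 1.25, aat_wet = 0.15,
                             ldd_cut = 4L) {
  stopifnot(haz_severe < haz_stunted, citrulline_low < citrulline_high)
  structure(list(haz_stunted = haz_stunted, haz_severe = haz_severe,
                 anemia_hb = anemia_hb, ferritin_low = ferritin_low,
                 crp_correction = crp_correction, crp_elevated = crp_elevated,
                 ferritin_factor = ferritin_factor,
                 citrulline_low = citrulline_low,
                 citrulline_high = citrulline_high,
                 ct_presence = ct_presence,
                 aat_dry = aat_dry, aat_wet = aat_wet,
                 ldd_cut = as.integer(ldd_cut)),
            class = "threshold_policy")
}

#' Stunting category from height-for-age Z-score
#'
#' Severe if HAZ <= -3, moderate if -3 < HAZ <= -2, normal otherwise.
#' Both cut-offs are inclusive downward.
#'
#' @param haz numeric vector of height-for-age Z-scores.
#' @param policy a [threshold_policy()].
#' @return factor with levels \code{normal}, \code{moderate}, \code{severe}
#'   (reference first).
#' @export
categorize_haz <- function(haz, policy = threshold_policy()) {
  stop_if_not_finite(haz, "haz")
  out <- ifelse(haz <= policy$haz_severe, "severe",
                ifelse(haz <= policy$haz_stunted, "moderate", "normal"))
  factor(out, levels = c("normal", "moderate", "severe"))
}

#' Dietary diversity score and low-diversity flag
#'
#' DDS is the number of the 7 food groups consumed in the last 24 h; low
#' dietary diversity (LDD) is a DDS strictly below the cut (default 4).
#'
#' @param food_groups logical/0-1 vector of length 7, or a matrix/data frame
#'   with 7 columns (one row per child).
#' @param policy a [threshold_policy()].
#' @return list with integer \code{dds} and logical \code{ldd}.
#' @export
dietary_diversity <- function(food_groups, policy = threshold_policy()) {
  if (is.null(dim(food_groups))) {
    if (length(food_groups) != 7L)
      stop("exactly 7 food-group indicators are required, got ",
           length(food_groups), call. = FALSE)
    dds <- as.integer(sum(food_groups > 0))
  } else {
    if (ncol(food_groups) != 7L)
      stop("exactly 7 food-group indicator columns are required, got ",
           ncol(food_groups), call. = FALSE)
    dds <- as.integer(rowSums(food_groups > 0))
  }
  list(dds = dds, ldd = dds < policy$ldd_cut)
}

#' Inflammation-corrected ferritin
#'
#' Ferritin is an acute-phase reactant; when CRP is strictly above the
#' correction threshold (6 mg/L) the measured value is multiplied by 0.67
#' before applying the low-iron cut-off (12 ug/L).
#'
#' @param ferritin measured ferritin, ug/L (non-negative).
#' @param crp C-reactive protein, mg/L (non-negative).
#' @param policy a [threshold_policy()].
#' @return list with numeric \code{corrected} and logical \code{low}.
#' @export
correct_ferritin <- function(ferritin, crp, policy = threshold_policy()) {
  if (any(ferritin < 0, na.rm = TRUE) || any(crp < 0, na.rm = TRUE))
    stop("ferritin and crp must be non-negative", call. = FALSE)
  corrected <- ifelse(crp > policy$crp_correction,
                      policy$ferritin_factor * ferritin, ferritin)
  list(corrected = corrected, low = corrected < policy$ferritin_low)
}

#' Classify hematological, inflammation and gut-function biomarkers
#'
#' @param hb hemoglobin g/dL (altitude-adjusted upstream).
#' @param crp C-reactive protein mg/L.
#' @param citrulline plasma citrulline umol/L.
#' @param aat_value fecal alpha-1-antitrypsin on the basis given by
#'   \code{aat_basis}.
#' @param aat_basis \code{"dry"} (mg/g dry weight) or \code{"wet"}.
#' @param ct_values numeric vector of qPCR cycle thresholds for the
#'   virulence-gene panel (one per assayed gene; NA = not run).
#' @param policy a [threshold_policy()].
#' @return list: \code{anemia}, \code{crp_elevated} (logicals),
#'   \code{citrulline_class} (\code{low}/\code{normal}/\code{elevated}),
#'   \code{aat_class} (\code{normal}/\code{elevated}),
#'   \code{pathogen_gene_count} (integer).
#' @export
classify_biomarkers <- function(hb, crp, citrulline, aat_value,
                                aat_basis = c("dry", "wet"),
                                ct_values = numeric(),
                                policy = threshold_policy()) {
  aat_basis <- match.arg(aat_basis)
  aat_cut <- if (aat_basis == "dry") policy$aat_dry else policy$aat_wet
  cit_class <- ifelse(citrulline < policy$citrulline_low, "low",
                      ifelse(citrulline > policy$citrulline_high,
                             "elevated", "normal"))
  list(anemia = hb < policy$anemia_hb,
       crp_elevated = crp > policy$crp_elevated,
       citrulline_class = cit_class,
       aat_class = ifelse(aat_value < aat_cut, "normal", "elevated"),
       pathogen_gene_count =
         as.integer(sum(ct_values < policy$ct_presence, na.rm = TRUE)))
}

#' Socioeconomic category from household assets
#'
#' Three-level score: (1) lowest if the household has no telephone or a
#' pounded-earth floor; (3) highest if (not lowest and) it has an internal
#' shower or an internal kitchen as a separate room; (2) otherwise.
#'
#' @param assets named list/vector with logical \code{telephone},
#'   \code{internal_shower}, \code{internal_kitchen} and character
#'   \code{floor} (\code{"pounded_earth"}, \code{"wood"}, \code{"concrete"}).
#' @return integer 1, 2 or 3.
#' @export
socioeconomic_category <- function(assets) {
  need <- c("telephone", "floor", "internal_shower", "internal_kitchen")
  missing_keys <- setdiff(need, names(assets))
  if (length(missing_keys))
    stop("missing asset keys: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  if (!isTRUE(as.logical(assets[["telephone"]])) ||
      identical(assets[["floor"]], "pounded_earth")) return(1L)
  if (isTRUE(as.logical(assets[["internal_shower"]])) ||
      isTRUE(as.logical(assets[["internal_kitchen"]]))) return(3L)
  2L
}

#' Overall developmental score
#'
#' Sum of the five ASQ-3 domain scores (communication, problem-solving,
#' personal-social, fine motor, gross motor), each on the 0--60 scale.
#'
#' @param domains numeric vector of 5 domain scores, or matrix/data frame
#'   with 5 columns.
#' @return integer sum(s).
#' @export
overall_asq <- function(domains) {
  x <- if (is.null(dim(domains))) matrix(domains, nrow = 1) else
    as.matrix(domains)
  if (ncol(x) != 5L)
    stop("five domain scores are required, got ", ncol(x), call. = FALSE)
  if (any(x < 0 | x > 60, na.rm = TRUE))
    stop("domain scores must lie in [0, 60]", call. = FALSE)
  out <- as.integer(rowSums(x))
  if (is.null(dim(domains))) out[1L] else out
}

#' Stunting-category counts and percentages
#'
#' @param cohort a cohort data frame with a \code{stunting_category} column
#'   (or a factor/character vector of categories).
#' @return data frame with \code{category}, \code{n}, \code{percent}
#'   (one decimal, half-up rounding).
#' @export
#' @examples
#' x <- rep(c("normal", "moderate", "severe"), c(197, 84, 68))
#' cohort_summary(x)   # 56.4 / 24.1 / 19.5
cohort_summary <- function(cohort) {
  cats <- if (is.data.frame(cohort)) cohort$stunting_category else cohort
  if (length(cats) == 0L) stop("empty cohort", call. = FALSE)
  cats <- factor(cats, levels = c("normal", "moderate", "severe"))
  n <- as.integer(table(cats))
  data.frame(category = levels(cats), n = n,
             percent = round_half_up(100 * n / sum(n), 1),
             stringsAsFactors = FALSE)
}
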