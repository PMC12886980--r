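# The four pre-specified structural topologies, each instantiated with one
# of the four microbiota constructs (shannon, streptococcaceae, pcoa1,
# cluster) substituted as the microbiome node.
#
# Edge sets, with the evidence behind the non-obvious ones:
#   simplest  : direct effects only -- SES, HAZ and the microbiome each
#               point at neurodevelopment; the three are exogenous and
#               covary freely.
#   simple    : adds the mediated routes SES -> HAZ, SES -> microbiome and
#               microbiome -> HAZ, so the SES and microbiome indirect
#               effects on neurodevelopment (through HAZ / the microbiome)
#               are estimable.
#   complex   : adds hemoglobin -> HAZ (anemia acts on growth), a BCAA
#               latent with BCAA -> HAZ (BCAAs support linear growth) and
#               BCAA -> microbiome (BCAA levels track lower diversity),
#               and AAT, age and reported birth size as direct covariates
#               of neurodevelopment.  No direct BCAA -> neuro or
#               hemoglobin -> neuro edge: their effects are mediated.
#   complex_path : the complex topology with every latent replaced by an
#               observed proxy -- rooms and maternal age at first pregnancy
#               for SES, leucine for BCAA, the overall score for the
#               neurodevelopment latent.

.neuro_ind <- c("comm", "ps", "pes", "fm", "gm")
.ses_ind <- c("ses_score_cat", "mother_edu", "mother_age_first_preg",
              "treated_water", "rooms")
.bcaa_ind <- c("alanine", "citrulline", "valine", "leucine", "isoleucine")
.constructs <- c("shannon", "streptococcaceae", "pcoa1", "cluster")

#' The four structural-model topologies for one microbiota construct
#'
#' @param construct one of \code{"shannon"}, \code{"streptococcaceae"},
#'   \code{"pcoa1"}, \code{"cluster"}; used as the observed microbiome node.
#' @return named list of 4 entries, each with \code{name}, \code{spec}
#'   (a [sem_spec()]), \code{construct} and a one-line \code{narrative}.
#' @export
build_model_catalog <- function(construct = "shannon") {
  if (!construct %in% .constructs)
    stop("unknown construct '", construct, "'; choose one of: ",
         paste(.constructs, collapse = ", "), call. = FALSE)
  mc <- construct
  neuro_meas <- list(neuro = .neuro_ind)
  ses_meas <- list(ses = .ses_ind)
  bcaa_meas <- list(bcaa = .bcaa_ind)

  simplest <- sem_spec(
    measurement = c(neuro_meas, ses_meas),
    structural = stats::setNames(list(c("ses", "haz", mc)), "neuro"))

  simple <- sem_spec(
    measurement = c(neuro_meas, ses_meas),
    structural = stats::setNames(
      list(c("ses", "haz", mc), c("ses", mc), "ses"),
      c("neuro", "haz", mc)))

  complex <- sem_spec(
    measurement = c(neuro_meas, ses_meas, bcaa_meas),
    structural = stats::setNames(
      list(c("ses", "haz", mc, "aat", "age", "birth_size"),
           c("ses", "hemoglobin", "bcaa", mc),
           c("ses", "bcaa")),
      c("neuro", "haz", mc)))

  complex_path <- sem_spec(
    structural = stats::setNames(
      list(c("rooms", "mother_age_first_preg", "haz", mc, "aat", "age",
             "birth_size"),
           c("hemoglobin", "leucine", "rooms", "mother_age_first_preg", mc),
           c("leucine", "rooms", "mother_age_first_preg")),
      c("overall_score", "haz", mc)))

  list(
    simplest = list(name = "simplest", spec = simplest, construct = mc,
                    narrative = "direct effects of SES, HAZ and the microbiome on neurodevelopment only"),
    simple = list(name = "simple", spec = simple, construct = mc,
                  narrative = "adds SES->HAZ, SES->microbiome and microbiome->HAZ mediated routes"),
    complex = list(name = "complex", spec = complex, construct = mc,
                   narrative = "adds hemoglobin, BCAA latent, AAT, age and reported birth size"),
    complex_path = list(name = "complex_path", spec = complex_path,
                        construct = mc,
                        narrative = "observed-proxy path model on the overall score, no latents"))
}
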