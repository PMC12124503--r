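#' Default ideal-family-size distribution
#'
#' Distribution over preference triples (ideal boys `B`, girls `G`,
#' either-gender `N`) used by the synthetic generator.  The support
#' respects the eligibility cap `B + G + N <= 9` and is skewed towards
#' son preference with a modal ideal family size of four, the shape
#' typical of Pakistani DHS rounds.
#'
#' @return data.frame with columns `B`, `G`, `N`, `prob`.
#' @export
default_ideal_dist <- function() {
  data.frame(
    B    = c(2L, 2L, 1L, 2L, 1L, 3L, 2L, 1L, 4L, 0L),
    G    = c(1L, 2L, 1L, 1L, 1L, 2L, 2L, 0L, 2L, 0L),
    N    = c(1L, 0L, 1L, 0L, 2L, 1L, 2L, 1L, 0L, 2L),
    prob = c(0.22, 0.18, 0.14, 0.10, 0.10, 0.08, 0.07, 0.05, 0.04, 0.02))
}

#' Default live-birth count distribution
#'
#' Number of live births per mother, support 0-8 (generator cap 12),
#' mean about 3.8 births - a high-fertility survey population.
#'
#' @return data.frame with columns `k`, `prob`.
#' @export
default_births_dist <- function() {
  data.frame(k = 0:8,
             prob = c(0.04, 0.08, 0.16, 0.20, 0.18, 0.13, 0.09, 0.07, 0.05))
}

default_covariate_spec <- function() {
  list(
    edu      = list(levels = 0:3, probs = c(0.49, 0.16, 0.20, 0.15)),
    wealth   = list(levels = 1:3, probs = c(0.45, 0.20, 0.35)),
    resid    = list(levels = 1:2, probs = c(0.47, 0.53)),
    prov     = list(levels = 1:6,
                    probs = c(0.28, 0.19, 0.19, 0.12, 0.08, 0.14)),
    mage     = list(levels = 1:4, probs = c(0.09, 0.60, 0.29, 0.02)),
    wsw      = list(levels = 0:1, probs = c(0.84, 0.16)),
    exc_m    = list(levels = 0:1, probs = c(0.81, 0.19)),
    empment  = list(levels = 0:1, probs = c(0.81, 0.19)),
    visit_hw = list(levels = 0:1, probs = c(0.45, 0.55)),
    age_ch   = list(levels = 0:4, probs = rep(0.2, 5)))
}

# Morbidity outcome names and the probit design used to generate them.
sim_outcomes <- c("ari", "cough", "diarrhea", "fever", "srb")
sim_design_cols <- c("(Intercept)", "ep", "ed", "eg", "eb", "bord", "mage")

#' Default outcome coefficient matrix
#'
#' Probit coefficients linking each morbidity outcome to the child-level
#' undesiredness flags (`ep`, `ed`, `eg`, `eb`), birth order and
#' maternal age group - the published multivariate-probit estimates for
#' this design, used here as the generating truth.
#'
#' @return 7 x 5 matrix, rows `(Intercept)`, `ep`, `ed`, `eg`, `eb`,
#'   `bord`, `mage`; columns `ari`, `cough`, `diarrhea`, `fever`, `srb`.
#' @export
default_outcome_beta <- function() {
  m <- cbind(
    ari      = c(0.7034, -0.1954, 0.3191, -0.0785, -0.0196, -0.2586, 0.1720),
    cough    = c(-0.1375, -0.2869, 0.0603, 0.1903, 0.2045, 0.0423, -0.0694),
    diarrhea = c(-0.8941, 0.1294, 0.1870, -0.1462, -0.0605, 0.0934, 0.0049),
    fever    = c(-0.0008, 0.2104, -0.0327, -0.1209, -0.4220, 0.1303, -0.1457),
    srb      = c(-0.8822, 0.0812, 0.1502, -0.1480, 0.0256, -0.0981, 0.0954))
  rownames(m) <- sim_design_cols
  m
}

#' Default residual correlation of the latent outcome errors
#'
#' @return 5 x 5 correlation matrix over `ari`, `cough`, `diarrhea`,
#'   `fever`, `srb`.
#' @export
default_outcome_sigma <- function() {
  s <- diag(5)
  r <- c(0.0562, 0.0010, -0.0039, 0.0747,   # ari  - others
         0.0462, 0.0760, -0.0254,           # cough- others
         -0.0269, 0.0026,                   # diar - fever, srb
         -0.0598)                           # fever- srb
  s[upper.tri(s)] <- r
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  dimnames(s) <- list(sim_outcomes, sim_outcomes)
  s
}

#' Synthetic-population configuration
#'
#' Bundles every parameter of the DHS-like generator.  All defaults are
#' the package's stated world: a high-fertility, son-preferring survey
#' population with a male live-birth fraction of 0.512, under-five death
#' probability 0.074, and morbidity outcomes drawn from the latent
#' multivariate-probit truth in [default_outcome_beta] /
#' [default_outcome_sigma].
#'
#' @param n_mothers number of mothers.
#' @param sex_ratio_male probability a live birth is male.
#' @param ideal_dist data.frame `B`, `G`, `N`, `prob` (triples must sum
#'   to at most 9).
#' @param births_dist data.frame `k`, `prob`, support within 0-12.
#' @param u5_death_prob per-child probability of dying before age five.
#' @param covariate_spec named list; each element
#'   `list(levels =, probs =)`.
#' @param outcome_beta coefficient matrix, one column per outcome, rows
#'   `(Intercept)`, `ep`, `ed`, `eg`, `eb`, `bord`, `mage`.
#' @param outcome_sigma residual correlation matrix of the latent errors.
#' @param treat_probs named marginal probabilities of the four treatment
#'   flags (`pnc`, `vita`, `tod`, `tofc`), generated independently.
#' @param dual_rule dual-excess rule, see [classify_children_sequential].
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_mothers = 100, seed = 1)
#' @export
sim_config <- function(n_mothers = 2000,
                       sex_ratio_male = 0.512,
                       ideal_dist = default_ideal_dist(),
                       births_dist = default_births_dist(),
                       u5_death_prob = 0.074,
                       covariate_spec = default_covariate_spec(),
                       outcome_beta = default_outcome_beta(),
                       outcome_sigma = default_outcome_sigma(),
                       treat_probs = c(pnc = 0.28, vita = 0.26,
                                       tod = 0.46, tofc = 0.40),
                       dual_rule = c("sex_and_parity", "both_sexes"),
                       seed = 1L) {
  dual_rule <- match.arg(dual_rule)
  if (!is_count(n_mothers)) stopf("'n_mothers' must be a non-negative count")
  if (!is_prob(sex_ratio_male) || sex_ratio_male <= 0 || sex_ratio_male >= 1)
    stopf("'sex_ratio_male' must lie in (0, 1)")
  if (!is_prob(u5_death_prob)) stopf("'u5_death_prob' must lie in [0, 1]")
  ideal_dist <- as.data.frame(ideal_dist)
  if (!all(c("B", "G", "N", "prob") %in% names(ideal_dist)))
    stopf("'ideal_dist' needs columns B, G, N, prob")
  if (any(ideal_dist$B + ideal_dist$G + ideal_dist$N > 9))
    stopf("'ideal_dist' has support with ideal family size > 9 (excluded)")
  if (abs(sum(ideal_dist$prob) - 1) > 1e-8 || any(ideal_dist$prob < 0))
    stopf("'ideal_dist$prob' must be a probability vector summing to 1")
  births_dist <- as.data.frame(births_dist)
  if (!all(c("k", "prob") %in% names(births_dist)))
    stopf("'births_dist' needs columns k, prob")
  if (any(births_dist$k < 0 | births_dist$k > 12))
    stopf("'births_dist' support must lie within 0..12")
  if (abs(sum(births_dist$prob) - 1) > 1e-8 || any(births_dist$prob < 0))
    stopf("'births_dist$prob' must be a probability vector summing to 1")
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (length(cs$levels) != length(cs$probs) ||
        abs(sum(cs$probs) - 1) > 1e-8 || any(cs$probs < 0))
      stopf("covariate_spec entry '%s' is not a valid distribution", nm)
  }
  outcome_beta <- as.matrix(outcome_beta)
  if (nrow(outcome_beta) != length(sim_design_cols))
    stopf("'outcome_beta' must have %d rows (%s)",
          length(sim_design_cols), paste(sim_design_cols, collapse = ", "))
  if (is.null(colnames(outcome_beta)))
    colnames(outcome_beta) <- sim_outcomes[seq_len(ncol(outcome_beta))]
  J <- ncol(outcome_beta)
  outcome_sigma <- as.matrix(outcome_sigma)
  if (!identical(dim(outcome_sigma), c(J, J)))
    stopf("'outcome_sigma' must be %d x %d to match 'outcome_beta'", J, J)
  tryCatch(check_corr_matrix(outcome_sigma),
           error = function(e) stopf("invalid 'outcome_sigma': %s",
                                     conditionMessage(e)))
  if (is.null(names(treat_probs)) || !all(treat_probs >= 0 & treat_probs <= 1))
    stopf("'treat_probs' must be a named vector of probabilities")
  structure(list(
    n_mothers = as.integer(n_mothers), sex_ratio_male = sex_ratio_male,
    ideal_dist = ideal_dist, births_dist = births_dist,
    u5_death_prob = u5_death_prob, covariate_spec = covariate_spec,
    outcome_beta = outcome_beta, outcome_sigma = outcome_sigma,
    treat_probs = treat_probs, dual_rule = dual_rule,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic DHS-like population config\n",
    "  mothers: %d, sex ratio (male): %.3f, under-5 death prob: %.3f\n",
    "  outcomes: %s\n  dual rule: %s, seed: %d\n"),
    x$n_mothers, x$sex_ratio_male, x$u5_death_prob,
    paste(colnames(x$outcome_beta), collapse = ", "), x$dual_rule, x$seed))
  invisible(x)
}
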