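#' Draw fertility preferences
#'
#' Samples preference triples (ideal boys, girls, either-gender) from
#' `config$ideal_dist`, using the current RNG state.
#'
#' @param config a [sim_config].
#' @param n number of mothers to draw.
#' @return data.table `B_m`, `G_m`, `N_m`, `C_m`.
#' @export
generate_preferences <- function(config, n = 1L) {
  stopifnot(inherits(config, "sim_config"))
  id <- config$ideal_dist
  ix <- sample.int(nrow(id), n, replace = TRUE, prob = id$prob)
  data.table::data.table(
    B_m = as.integer(id$B[ix]), G_m = as.integer(id$G[ix]),
    N_m = as.integer(id$N[ix]),
    C_m = as.integer(id$B[ix] + id$G[ix] + id$N[ix]))
}

#' Draw one mother's birth history
#'
#' The number of live births comes from `config$births_dist`; each child
#' is male with probability `config$sex_ratio_male` and dies before age
#' five independently with probability `config$u5_death_prob`.
#'
#' @param pref the mother's [fertility_pref] (carried through unused by
#'   the sampling itself; preferences do not alter fertility here).
#' @param config a [sim_config].
#' @return data.table `birth_order`, `sex` (`"M"`/`"F"`), `alive` (0/1).
#' @export
generate_birth_history <- function(pref, config) {
  stopifnot(inherits(config, "sim_config"))
  bd <- config$births_dist
  k <- bd$k[sample.int(nrow(bd), 1L, prob = bd$prob)]
  if (k == 0) {
    return(data.table::data.table(birth_order = integer(0),
                                  sex = character(0), alive = integer(0)))
  }
  sex <- ifelse(runif(k) < config$sex_ratio_male, "M", "F")
  alive <- as.integer(runif(k) >= config$u5_death_prob)
  data.table::data.table(birth_order = seq_len(k), sex = sex, alive = alive)
}

#' Draw correlated binary outcomes from the latent-Gaussian model
#'
#' For each design row `x`, draws `eps ~ MVN(0, sigma)` and sets
#' `y_j = 1` iff `x %*% beta[, j] + eps_j > 0` - the data-generating
#' process the multivariate probit assumes.
#'
#' @param X numeric design matrix (rows = children), columns matching
#'   `rownames(beta)`.
#' @param beta coefficient matrix, one column per outcome.
#' @param sigma residual correlation matrix (J x J).
#' @return integer 0/1 matrix, `nrow(X)` x `ncol(beta)`.
#' @export
generate_outcomes <- function(X, beta, sigma) {
  X <- as.matrix(X); beta <- as.matrix(beta)
  if (ncol(X) != nrow(beta))
    stopf("design has %d columns but beta has %d rows", ncol(X), nrow(beta))
  J <- ncol(beta)
  if (!identical(dim(as.matrix(sigma)), c(J, J)))
    stopf("sigma must be %d x %d", J, J)
  check_corr_matrix(sigma)
  n <- nrow(X)
  if (n == 0) return(matrix(integer(0), 0, J,
                            dimnames = list(NULL, colnames(beta))))
  L <- chol(sigma)                       # upper triangular, sigma = t(L) L
  eps <- matrix(rnorm(n * J), n, J) %*% L
  y <- (X %*% beta + eps > 0) * 1L
  colnames(y) <- colnames(beta)
  y
}

#' Simulate a full DHS-like population
#'
#' Deterministic given `config$seed`.  Draw order: preferences, birth
#' counts, maternal covariates (in `covariate_spec` order), child sexes,
#' child deaths, child ages, latent outcome errors, treatment flags.
#' Child-level undesiredness flags are computed with the sequential
#' classifier and used - together with birth order and maternal age -
#' as the design for the latent-Gaussian outcomes.
#'
#' @param config a [sim_config].
#' @return object of class `sim_population`: list with data.tables
#'   `mothers` and `children` and a `truth` list (generating `beta`,
#'   `sigma`, `treat_probs`, and the analytic excess prevalences).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mothers
  cs <- config$covariate_spec
  mother_cov_names <- setdiff(names(cs), "age_ch")

  if (n == 0) {
    mothers <- data.table::data.table(
      mother_id = integer(0), B_m = integer(0), G_m = integer(0),
      N_m = integer(0), C_m = integer(0))
    for (nm in mother_cov_names) mothers[[nm]] <- integer(0)
    children <- empty_children(config)
    return(new_sim_population(mothers, children, config))
  }

  prefs <- generate_preferences(config, n)
  bd <- config$births_dist
  kvec <- bd$k[sample.int(nrow(bd), n, replace = TRUE, prob = bd$prob)]
  mothers <- data.table::data.table(mother_id = seq_len(n))
  mothers <- cbind(mothers, prefs)
  for (nm in mother_cov_names) {
    sp <- cs[[nm]]
    mothers[[nm]] <- sp$levels[sample.int(length(sp$levels), n,
                                          replace = TRUE, prob = sp$probs)]
  }

  n_ch <- sum(kvec)
  if (n_ch == 0) {
    children <- empty_children(config)
    return(new_sim_population(mothers, children, config))
  }
  children <- data.table::data.table(
    mother_id = rep(seq_len(n), kvec),
    birth_order = sequence(kvec[kvec > 0]))
  children[, sex := ifelse(runif(n_ch) < config$sex_ratio_male, "M", "F")]
  children[, alive := as.integer(runif(n_ch) >= config$u5_death_prob)]
  if (!is.null(cs$age_ch)) {
    sp <- cs$age_ch
    children[, age_ch := sp$levels[sample.int(length(sp$levels), n_ch,
                                              replace = TRUE,
                                              prob = sp$probs)]]
  }
  children[, sex_ch := as.integer(sex == "F")]
  children[, bord := birth_order]

  flags <- classify_population(mothers, children, config$dual_rule)
  children <- merge(
    children,
    flags[, c("mother_id", "birth_order", "excess_gender", "excess_parity",
              "excess_dual", "excess_boys", "excess_girls"), with = FALSE],
    by = c("mother_id", "birth_order"), sort = FALSE)
  data.table::setorder(children, mother_id, birth_order)

  mage <- mothers$mage[match(children$mother_id, mothers$mother_id)]
  X <- cbind(1, children$excess_parity, children$excess_dual,
             children$excess_girls, children$excess_boys,
             children$bord, mage)
  colnames(X) <- sim_design_cols
  y <- generate_outcomes(X, config$outcome_beta, config$outcome_sigma)
  for (j in colnames(y)) children[[j]] <- y[, j]
  for (tn in names(config$treat_probs))
    children[[tn]] <- rbinom(n_ch, 1L, config$treat_probs[[tn]])

  new_sim_population(mothers, children, config)
}

empty_children <- function(config) {
  ch <- data.table::data.table(
    mother_id = integer(0), birth_order = integer(0), sex = character(0),
    alive = integer(0), age_ch = integer(0), sex_ch = integer(0),
    bord = integer(0), excess_gender = integer(0), excess_parity = integer(0),
    excess_dual = integer(0), excess_boys = integer(0),
    excess_girls = integer(0))
  for (j in colnames(config$outcome_beta)) ch[[j]] <- integer(0)
  for (tn in names(config$treat_probs)) ch[[tn]] <- integer(0)
  ch
}

new_sim_population <- function(mothers, children, config) {
  truth <- list(
    beta = config$outcome_beta, sigma = config$outcome_sigma,
    treat_probs = config$treat_probs,
    analytic_prevalence = if (config$dual_rule == "sex_and_parity")
      analytic_excess_prevalence(config) else NULL)
  structure(list(mothers = mothers, children = children, truth = truth,
                 config = config), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Synthetic population: %d mothers, %d children\n",
              nrow(x$mothers), nrow(x$children)))
  invisible(x)
}

#' Exact expected prevalence of the undesiredness categories
#'
#' Enumerates, by dynamic programming over the living-children state,
#' the exact expectation of each excess category under a [sim_config]:
#' preference triple x number of births x sex sequence x death pattern,
#' with deaths realised immediately after the child's own birth (the
#' generator's event order).  Serves as the analytic oracle for
#' [aggregate_excess] on simulated populations.  Only the default
#' `"sex_and_parity"` dual rule is supported (the `"both_sexes"` child
#' rule depends on the mother's final state and is not a per-birth
#' functional of the DP state).
#'
#' @param config a [sim_config]; `births_dist` support must be finite
#'   and within 0-12 (enforced at construction).
#' @return list with data.tables `child` and `mother` (`category`,
#'   `percent`), and `expected_children` (mean births per mother).
#' @export
analytic_excess_prevalence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dual_rule != "sex_and_parity")
    stopf("analytic prevalence implemented for dual_rule = 'sex_and_parity' only")
  p_male <- config$sex_ratio_male
  d <- config$u5_death_prob
  id <- config$ideal_dist
  bd <- config$births_dist
  kmax <- max(bd$k)
  cats <- c("excess_boys", "excess_girls", "excess_parity", "excess_dual")
  exp_child <- setNames(numeric(4), cats)
  p_mother <- setNames(numeric(4), cats)

  for (t in seq_len(nrow(id))) {
    pt <- id$prob[t]
    if (pt == 0) next
    pref <- fertility_pref(id$B[t], id$G[t], id$N[t])
    # P[b+1, g+1, fb+1]: prob of living-boy/girl counts and flag bits
    # (1 = boys, 2 = girls, 4 = parity, 8 = dual) after each birth.
    P <- array(0, dim = c(kmax + 1, kmax + 1, 16))
    P[1, 1, 1] <- 1
    # probability that this pref contributes at each k of births_dist
    pk_at <- setNames(bd$prob, bd$k)
    for (step in seq_len(max(kmax, 0))) {
      if (kmax == 0) break
      newP <- array(0, dim = dim(P))
      bgrid <- row(matrix(0, kmax + 1, kmax + 1)) - 1L
      ggrid <- col(matrix(0, kmax + 1, kmax + 1)) - 1L
      for (s in c("M", "F")) {
        ps <- if (s == "M") p_male else 1 - p_male
        own  <- if (s == "M") bgrid + 1L else ggrid + 1L
        ownq <- if (s == "M") pref$B else pref$G
        oth  <- if (s == "M") ggrid else bgrid
        othq <- if (s == "M") pref$G else pref$B
        consumed <- pmin(pmax(0L, oth - othq), pref$N)
        egf <- own > ownq + (pref$N - consumed)
        epf <- bgrid + ggrid + 1L > pref$C
        bits <- (egf & s == "M") * 1L + (egf & s == "F") * 2L +
          epf * 4L + (egf & epf) * 8L
        for (fb in 0:15) {
          mass <- P[, , fb + 1]
          if (all(mass == 0)) next
          # child-level flag expectations (flag set at birth, before the
          # survival draw), weighted by P(reaching at least `step` births)
          w <- sum(pk_at[as.numeric(names(pk_at)) >= step])
          contrib <- pt * ps * w * mass
          exp_child["excess_boys"]   <- exp_child["excess_boys"] +
            sum(contrib[egf & s == "M"])
          exp_child["excess_girls"]  <- exp_child["excess_girls"] +
            sum(contrib[egf & s == "F"])
          exp_child["excess_parity"] <- exp_child["excess_parity"] +
            sum(contrib[epf])
          exp_child["excess_dual"]   <- exp_child["excess_dual"] +
            sum(contrib[egf & epf])
          # transitions: survive (counts grow) or die (counts frozen)
          for (ii in which(mass > 0)) {
            b <- bgrid[ii]; g <- ggrid[ii]
            m <- mass[ii]
            nb <- bits[ii]
            fb2 <- bitwOr(fb, nb)
            if (s == "M") {
              newP[b + 2, g + 1, fb2 + 1] <- newP[b + 2, g + 1, fb2 + 1] +
                m * ps * (1 - d)
              newP[b + 1, g + 1, fb2 + 1] <- newP[b + 1, g + 1, fb2 + 1] +
                m * ps * d
            } else {
              newP[b + 1, g + 2, fb2 + 1] <- newP[b + 1, g + 2, fb2 + 1] +
                m * ps * (1 - d)
              newP[b + 1, g + 1, fb2 + 1] <- newP[b + 1, g + 1, fb2 + 1] +
                m * ps * d
            }
          }
        }
      }
      # mothers whose birth count equals `step` stop here
      pk <- pk_at[as.character(step)]
      if (!is.na(pk) && pk > 0) {
        fbmass <- apply(newP, 3, sum)
        for (fb in 0:15) {
          if (fbmass[fb + 1] == 0) next
          if (bitwAnd(fb, 1L) > 0)
            p_mother["excess_boys"] <- p_mother["excess_boys"] +
              pt * pk * fbmass[fb + 1]
          if (bitwAnd(fb, 2L) > 0)
            p_mother["excess_girls"] <- p_mother["excess_girls"] +
              pt * pk * fbmass[fb + 1]
          if (bitwAnd(fb, 4L) > 0)
            p_mother["excess_parity"] <- p_mother["excess_parity"] +
              pt * pk * fbmass[fb + 1]
          if (bitwAnd(fb, 8L) > 0)
            p_mother["excess_dual"] <- p_mother["excess_dual"] +
              pt * pk * fbmass[fb + 1]
        }
      }
      P <- newP
    }
  }
  ek <- sum(bd$k * bd$prob)
  child <- data.table::data.table(
    category = cats,
    percent = if (ek > 0) 100 * unname(exp_child) / ek else rep(0, 4))
  mother <- data.table::data.table(category = cats,
                                   percent = 100 * unname(p_mother))
  list(child = child, mother = mother, expected_children = ek)
}

#' Write a simulated population to disk
#'
#' Emits `mothers.csv`, `children.csv` and `truth.json` (generating
#' coefficients, residual correlation, treatment marginals and analytic
#' prevalences) into `dir`.  Output is byte-deterministic for a given
#' population.
#'
#' @param pop a `sim_population`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("mothers.csv", "children.csv", "truth.json"))
  data.table::fwrite(pop$mothers, paths[1])
  data.table::fwrite(pop$children, paths[2])
  truth <- pop$truth
  json <- list(
    beta = as.data.frame(truth$beta), sigma = as.data.frame(truth$sigma),
    treat_probs = as.list(truth$treat_probs),
    analytic_prevalence = if (!is.null(truth$analytic_prevalence)) list(
      child = truth$analytic_prevalence$child,
      mother = truth$analytic_prevalence$mother,
      expected_children = truth$analytic_prevalence$expected_children))
  jsonlite::write_json(json, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
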