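#' Pipeline run configuration
#'
#' Builds and validates the configuration for [run_pipeline], either
#' programmatically or from a YAML file.  Exactly one data source is
#' allowed: CSV input paths (`input$mothers`, `input$children`) or a
#' synthetic-population specification (`sim`, a list of [sim_config]
#' arguments).  The global `seed` propagates to every stochastic stage.
#'
#' @param sim list of [sim_config] arguments (or `NULL`).
#' @param input list with `mothers`/`children` CSV paths (or `NULL`).
#' @param stages stages to execute, in order, from `"simulate"`,
#'   `"classify"`, `"tables"`, `"pca"`, `"mvprobit"`, `"ml"`.
#' @param dual_rule dual-excess rule.
#' @param pca list: `n_keep` (optional component override).
#' @param mvp list: `outcomes`, `regressors`, `draws`.
#' @param ml list: `models`, `outcomes`, `features`, `ntree`, `hidden`,
#'   `epochs`, `lr`, `fraction`.
#' @param seed global seed.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = list(), input = NULL,
                       stages = c("simulate", "classify", "tables", "pca",
                                  "mvprobit", "ml"),
                       dual_rule = "sex_and_parity",
                       pca = list(), mvp = list(), ml = list(),
                       seed = 1L, out_dir = "undesired_run") {
  if (!is.null(input) && length(sim) > 0)
    stopf("provide exactly one of 'input' paths or a 'sim' specification")
  stages <- match.arg(stages, several.ok = TRUE)
  mvp_def <- list(outcomes = sim_outcomes,
                  regressors = c("excess_parity", "excess_dual",
                                 "excess_girls", "excess_boys",
                                 "bord", "mage"),
                  draws = 100)
  ml_def <- list(models = c("rf", "nn"),
                 outcomes = sim_outcomes,
                 features = c("excess_parity", "excess_dual", "excess_girls",
                              "excess_boys", "bord", "mage", "edu", "wealth",
                              "resid", "prov", "age_ch", "sex_ch"),
                 ntree = 500, hidden = 8, epochs = 200, lr = 0.1,
                 fraction = 0.7)
  structure(list(
    sim = sim, input = input, stages = stages, dual_rule = dual_rule,
    pca = pca, mvp = modifyList(mvp_def, mvp), ml = modifyList(ml_def, ml),
    seed = as.integer(seed), out_dir = out_dir), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config].
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Validate input CSV tables against the pipeline schema
#'
#' Checks column presence and coding of `mothers.csv` / `children.csv`.
#' Fatal problems (missing required columns, unreadable files) are
#' collected in `errors`; recoverable codings - e.g. child sex coded
#' 1/2 instead of `M`/`F` - are remapped with a warning recorded in
#' `warnings`.
#'
#' @param mothers_path,children_path CSV paths.
#' @return list `mothers`, `children` (data.tables, possibly recoded),
#'   `errors`, `warnings`.
#' @export
validate_input <- function(mothers_path, children_path) {
  errors <- character(0); warnings_ <- character(0)
  for (p in c(mothers_path, children_path))
    if (!file.exists(p)) stopf("input file '%s' does not exist", p)
  mo <- data.table::fread(mothers_path)
  ch <- data.table::fread(children_path)
  for (col in c("mother_id", "B_m", "G_m", "N_m"))
    if (!col %in% names(mo))
      errors <- c(errors, sprintf("mothers: missing column '%s'", col))
  for (col in c("mother_id", "birth_order", "sex", "alive"))
    if (!col %in% names(ch))
      errors <- c(errors, sprintf("children: missing column '%s'", col))
  if ("sex" %in% names(ch)) {
    sx <- ch$sex
    if (is.numeric(sx) || all(sx %in% c("1", "2", NA))) {
      ch$sex <- c("M", "F")[as.integer(sx)]
      msg <- "children: sex coded 1/2 remapped to M/F (DHS recode)"
      warnings_ <- c(warnings_, msg)
      warnf(msg)
    } else if (!all(sx %in% c("M", "F", NA))) {
      errors <- c(errors, "children: sex must be coded M/F (or DHS 1/2)")
    }
  }
  if ("alive" %in% names(ch) && !all(ch$alive %in% c(0, 1, NA)))
    errors <- c(errors, "children: 'alive' must be 0/1")
  list(mothers = mo, children = ch, errors = errors, warnings = warnings_)
}

# documented binarisation of the mixed covariates for the tetrachoric /
# PCA stage (the association stage operates on binary indicators)
binarize_for_pca <- function(dt) {
  out <- data.table::data.table(
    ep = dt$excess_parity, ed = dt$excess_dual, eg = dt$excess_girls,
    eb = dt$excess_boys)
  add <- function(name, x) if (!is.null(x)) out[[name]] <<- as.integer(x)
  add("bord_hi", dt$bord > stats::median(dt$bord))
  add("mage_hi", if ("mage" %in% names(dt)) dt$mage > 2)
  add("edu_any", if ("edu" %in% names(dt)) dt$edu > 0)
  add("wealth_rich", if ("wealth" %in% names(dt)) dt$wealth >= 3)
  add("resid_rural", if ("resid" %in% names(dt)) dt$resid == 2)
  add("prov_punjab", if ("prov" %in% names(dt)) dt$prov == 1)
  add("age_ch_hi", if ("age_ch" %in% names(dt)) dt$age_ch > 2)
  for (v in c("wsw", "exc_m", "empment", "visit_hw", "sex_ch"))
    add(v, if (v %in% names(dt)) dt[[v]])
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> eligibility filter -> sequential
#' classification -> descriptive tables -> tetrachoric/KMO/Bartlett/PCA
#' -> multivariate probit -> RF/NN evaluation, writing every stage's
#' artifact into `config$out_dir` together with a `manifest.json`
#' recording the package version, seeds, per-stage row counts, the
#' filter report and an MD5 hash of every artifact.  Deterministic for
#' a fixed configuration.
#'
#' @param config a [run_config].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("undesired")),
    seed = config$seed, stages = config$stages, counts = list())
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    path
  }
  files <- character(0)

  # --- data stage -----------------------------------------------------
  if (!is.null(config$input)) {
    vi <- validate_input(config$input$mothers, config$input$children)
    if (length(vi$errors))
      stopf("stage 'input' failed:\n  %s", paste(vi$errors, collapse = "\n  "))
    mothers <- vi$mothers; children <- vi$children
    manifest$input_warnings <- vi$warnings
  } else {
    sim_args <- modifyList(list(seed = config$seed,
                                dual_rule = config$dual_rule), config$sim)
    cfg <- do.call(sim_config, sim_args)
    pop <- simulate_population(cfg)
    mothers <- pop$mothers; children <- pop$children
    files <- c(files, write_population(pop, config$out_dir))
  }
  manifest$counts$mothers_raw <- nrow(mothers)
  manifest$counts$children_raw <- nrow(children)

  filt <- apply_eligibility_filters(mothers, children)
  mothers <- filt$mothers; children <- filt$children
  manifest$filter_report <- as.data.frame(filt$report)
  manifest$counts$mothers <- nrow(mothers)
  manifest$counts$children <- nrow(children)

  # --- classify -------------------------------------------------------
  flags <- NULL
  if ("classify" %in% config$stages) {
    flags <- classify_population(mothers, children, config$dual_rule)
    prev <- aggregate_excess(flags, n_mothers = nrow(mothers))
    files <- c(files,
      emit("excess_flags.csv", function(p) data.table::fwrite(flags, p)),
      emit("excess_prevalence.json", function(p)
        jsonlite::write_json(list(child = prev$child, mother = prev$mother),
                             p, digits = NA, dataframe = "columns")))
    flagcols <- c("excess_gender", "excess_parity", "excess_dual",
                  "excess_boys", "excess_girls")
    drop <- intersect(flagcols, names(children))
    if (length(drop)) children[, (drop) := NULL]
    children <- merge(children,
                      flags[, c("mother_id", "birth_order", flagcols),
                            with = FALSE],
                      by = c("mother_id", "birth_order"), sort = FALSE)
  }

  # merged child-level analysis table (flags + maternal covariates)
  analysis <- merge(children, mothers, by = "mother_id", sort = FALSE)
  data.table::setorder(analysis, mother_id, birth_order)

  # --- tables ---------------------------------------------------------
  if ("tables" %in% config$stages) {
    vars <- intersect(c("excess_girls", "excess_parity", "excess_dual",
                        "excess_boys", "edu", "exc_m", "empment", "wealth",
                        "bord", "resid", "visit_hw", "prov", "mage", "wsw",
                        "age_ch", "sex_ch"), names(analysis))
    files <- c(files,
      emit("table1_moments.csv", function(p)
        data.table::fwrite(summarize_variables(analysis, vars), p)))
    bg <- intersect(c("sex_ch", "mage", "resid", "prov", "wealth", "edu",
                      "exc_m", "wsw"), names(analysis))
    ct <- data.table::rbindlist(lapply(bg, function(v)
      cbind(background = v, crosstab_background(analysis, v))))
    files <- c(files,
      emit("crosstab_background.csv", function(p) data.table::fwrite(ct, p)))
    oc <- intersect(c(sim_outcomes, "pnc", "vita", "tod", "tofc"),
                    names(analysis))
    pv <- data.table::rbindlist(lapply(oc, function(o)
      prevalence_by_excess(analysis, o)))
    files <- c(files,
      emit("prevalence_by_excess.csv", function(p)
        data.table::fwrite(pv, p)))
  }

  # --- association / PCA ---------------------------------------------
  selected <- NULL
  if ("pca" %in% config$stages) {
    bin <- binarize_for_pca(analysis)
    corr <- tetrachoric_matrix(bin)
    km <- kmo(corr)
    bt <- bartlett_sphericity(corr, nrow(bin))
    pc <- pca_corr(corr, n_keep = config$pca$n_keep)
    selected <- select_features(pc)
    files <- c(files,
      emit("corr_matrix.csv", function(p)
        data.table::fwrite(data.table::as.data.table(unclass(corr),
                                                     keep.rownames = "var"),
                           p)),
      emit("pca_scree.csv", function(p)
        data.table::fwrite(data.table::data.table(
          component = seq_along(pc$eigenvalues),
          eigenvalue = pc$eigenvalues,
          percent_variance = pc$percent_variance), p)),
      emit("pca_contributions.csv", function(p)
        data.table::fwrite(data.table::as.data.table(pc$contributions,
                                                     keep.rownames = "var"),
                           p)),
      emit("selected_features.json", function(p)
        jsonlite::write_json(list(
          kmo_overall = km$overall, bartlett = bt,
          retained_components = pc$retained, selected = selected),
          p, auto_unbox = TRUE, digits = NA)))
    manifest$kmo <- km$overall
  }

  # --- multivariate probit -------------------------------------------
  if ("mvprobit" %in% config$stages) {
    mvp <- config$mvp
    fit <- mvp_fit(analysis, outcomes = mvp$outcomes,
                   regressors = mvp$regressors, R = mvp$draws,
                   seed = derive_seed(config$seed, 101L))
    files <- c(files,
      emit("mvp_fit.csv", function(p) { format_fit(fit, p); invisible() }),
      emit("mvp_fit.json", function(p)
        jsonlite::write_json(list(
          logLik = fit$logLik, convergence = fit$convergence,
          n = fit$n, R = fit$R, table = fit$table),
          p, auto_unbox = TRUE, digits = NA, dataframe = "columns")))
    manifest$mvp_logLik <- fit$logLik
  }

  # --- ML evaluation --------------------------------------------------
  if ("ml" %in% config$stages) {
    ml <- config$ml
    feats <- intersect(ml$features, names(analysis))
    perf <- list(); imp <- list()
    for (o in intersect(ml$outcomes, names(analysis))) {
      dat <- analysis[!is.na(analysis[[o]])]
      sp <- split_train_test(dat, ml$fraction,
                             seed = derive_seed(config$seed, 211L),
                             stratify_by = o)
      if ("rf" %in% ml$models) {
        rf <- train_rf(sp$train, o, feats, ntree = ml$ntree,
                       seed = derive_seed(config$seed, 307L))
        perf[[paste0(o, "_rf")]] <- evaluate_model(rf, sp$test)
        for (meth in c("mean_decrease_accuracy", "mean_decrease_gini"))
          imp[[paste0(o, "_rf_", meth)]] <- cbind(
            outcome = o, model = "rf", method = meth,
            var_importance(rf, sp$test, meth,
                           seed = derive_seed(config$seed, 401L)))
      }
      if ("nn" %in% ml$models) {
        nn <- train_mlp(sp$train, o, feats, hidden = ml$hidden,
                        epochs = ml$epochs, lr = ml$lr,
                        seed = derive_seed(config$seed, 503L))
        perf[[paste0(o, "_nn")]] <- evaluate_model(nn, sp$test)
        imp[[paste0(o, "_nn")]] <- cbind(
          outcome = o, model = "nn", method = "mean_decrease_accuracy",
          var_importance(nn, sp$test, "mean_decrease_accuracy",
                         seed = derive_seed(config$seed, 401L)))
      }
    }
    files <- c(files,
      emit("ml_performance.csv", function(p)
        data.table::fwrite(data.table::rbindlist(perf), p)),
      emit("ml_importance.csv", function(p) {
        it <- data.table::rbindlist(imp)
        it[, rank := seq_len(.N), by = c("outcome", "model", "method")]
        data.table::fwrite(it, p)
      }))
  }

  manifest$files <- as.list(setNames(
    unname(tools::md5sum(sort(unique(files)))),
    basename(sort(unique(files)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(manifest)
}

#' Command-line entry point
#'
#' `undesired_cli(c("run", "--config", "run.yaml"))` executes the
#' pipeline described by a YAML configuration; `--seed` and `--out`
#' override the file.  Exit status (returned integer): 0 ok, 1
#' configuration error, 2 stage failure.
#'
#' @param args character vector of CLI arguments.
#' @return integer status, invisibly.
#' @export
undesired_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  if (length(args) == 0 || args[1] != "run") {
    message("usage: undesired run --config <run.yaml> [--seed N] [--out dir]")
    return(invisible(1L))
  }
  cfg <- tryCatch({
    path <- get_opt("--config")
    if (is.null(path)) stopf("--config is required")
    cc <- read_run_config(path)
    if (!is.null(s <- get_opt("--seed"))) cc$seed <- as.integer(s)
    if (!is.null(o <- get_opt("--out"))) cc$out_dir <- o
    cc
  }, error = function(e) { message("config error: ",
                                   conditionMessage(e)); NULL })
  if (is.null(cfg)) return(invisible(1L))
  ok <- tryCatch({ run_pipeline(cfg); TRUE },
                 error = function(e) { message("stage failure: ",
                                               conditionMessage(e)); FALSE })
  invisible(if (ok) 0L else 2L)
}
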