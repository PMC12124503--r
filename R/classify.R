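#' Fertility preference of a mother
#'
#' A mother's stated ideal family composition: `B` ideal boys, `G` ideal
#' girls and `N` children of either gender, so the ideal family size is
#' `C = B + G + N`.  Respondents with `C > 9` are outside the eligible
#' range and are rejected here (the survey exclusion rule).
#'
#' @param B,G,N non-negative integer counts.
#' @return object of class `fertility_pref` (a named list with `B`, `G`,
#'   `N`, `C`).
#' @examples
#' fertility_pref(2, 1, 1) # ideal family size 4
#' @export
fertility_pref <- function(B, G, N) {
  for (x in list(B = B, G = G, N = N))
    if (!is_count(x)) stopf("B, G and N must be non-negative integers")
  C <- B + G + N
  if (C > 9)
    stopf("ideal family size %d exceeds the eligibility cap of 9", C)
  structure(list(B = as.integer(B), G = as.integer(G), N = as.integer(N),
                 C = as.integer(C)),
            class = "fertility_pref")
}

#' @export
print.fertility_pref <- function(x, ...) {
  cat(sprintf("Fertility preference: %d boys + %d girls + %d either = %d\n",
              x$B, x$G, x$N, x$C))
  invisible(x)
}

# Gender-excess decision for one new birth, given living counts just
# before it.  Either-gender slots are shared: the other sex consumes
# min(max(0, other - other_quota), N) of them, and the new child is in
# excess when its own living same-sex count (including itself) exceeds
# own quota + remaining either slots.
gender_excess_rule <- function(sex, boys_before, girls_before, pref) {
  if (is.na(sex)) return(FALSE)
  if (sex == "M") {
    own <- boys_before + 1L; own_q <- pref$B
    oth <- girls_before;     oth_q <- pref$G
  } else {
    own <- girls_before + 1L; own_q <- pref$G
    oth <- boys_before;       oth_q <- pref$B
  }
  consumed <- min(max(0L, oth - oth_q), pref$N)
  own > own_q + (pref$N - consumed)
}

#' Sequential child-level undesiredness classification
#'
#' Replays a mother's reproductive history as an ordered sequence of
#' birth and death events and flags each child **at the moment of its
#' birth**:
#'
#' * *gender excess* - the count of living same-sex children, including
#'   the newborn, exceeds the sex-specific quota plus the either-gender
#'   slots not already consumed by the other sex (either-gender slots
#'   are consumed greedily in birth order once a sex quota is full);
#' * *parity excess* - living children including the newborn exceed the
#'   ideal family size;
#' * *dual excess* - under the default `"sex_and_parity"` rule, both of
#'   the above; under `"both_sexes"`, the child is gender-excess and the
#'   mother ends up with gender-excess children of both sexes.
#'
#' A death frees the deceased child's slot for subsequent births but
#' never revises a flag already assigned.  Children with missing sex are
#' excluded from the gender computation but still count towards parity.
#'
#' @param pref a [fertility_pref].
#' @param events either a character vector with elements `"B"` (boy
#'   birth), `"G"` (girl birth) and `"D<k>"` (death of the child with
#'   birth order `k`), or a data.frame with columns `event`
#'   (`"birth"`/`"death"`), `sex` and `child`.
#' @param dual_rule `"sex_and_parity"` (default) or `"both_sexes"`.
#' @return data.table with one row per birth: `birth_order`, `sex`,
#'   `excess_gender`, `excess_parity`, `excess_dual`, `excess_boys`,
#'   `excess_girls` (0/1 integers).
#' @examples
#' # six-child history: four boys, one dies, then a girl and a last boy
#' classify_children_sequential(
#'   fertility_pref(2, 1, 1),
#'   c("B", "B", "B", "B", "D1", "G", "B"))
#' @export
classify_children_sequential <- function(pref, events,
                                         dual_rule = c("sex_and_parity",
                                                       "both_sexes")) {
  dual_rule <- match.arg(dual_rule)
  stopifnot(inherits(pref, "fertility_pref"))
  events <- parse_events(events)
  sex <- character(0); alive <- logical(0)
  eg <- ep <- logical(0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$event == "birth") {
      b <- sum(alive & !is.na(sex) & sex == "M")
      g <- sum(alive & !is.na(sex) & sex == "F")
      n_live <- sum(alive)
      eg <- c(eg, gender_excess_rule(ev$sex, b, g, pref))
      ep <- c(ep, n_live + 1L > pref$C)
      sex <- c(sex, ev$sex); alive <- c(alive, TRUE)
    } else {
      k <- ev$child
      if (is.na(k) || k < 1 || k > length(alive))
        stopf("death event refers to unknown child %s", ev$child)
      if (!alive[k]) stopf("death event for already-dead child %d", k)
      alive[k] <- FALSE
    }
  }
  male <- !is.na(sex) & sex == "M"
  female <- !is.na(sex) & sex == "F"
  dual <- switch(dual_rule,
    sex_and_parity = eg & ep,
    both_sexes = eg & ((male & any(eg & female)) | (female & any(eg & male))))
  data.table::data.table(
    birth_order = seq_along(sex), sex = sex,
    excess_gender = as.integer(eg), excess_parity = as.integer(ep),
    excess_dual = as.integer(dual),
    excess_boys = as.integer(eg & male),
    excess_girls = as.integer(eg & female))
}

parse_events <- function(events) {
  if (is.data.frame(events)) {
    stopifnot(all(c("event", "sex", "child") %in% names(events)))
    return(as.data.frame(events))
  }
  if (!is.character(events)) stopf("'events' must be character or data.frame")
  birth <- events %in% c("B", "G") | is.na(events)
  data.frame(
    event = ifelse(birth, "birth", "death"),
    sex = ifelse(birth, ifelse(is.na(events), NA, chartr("BG", "MF", events)),
                 NA_character_),
    child = ifelse(birth, NA_integer_,
                   suppressWarnings(as.integer(sub("^D", "", events)))),
    stringsAsFactors = FALSE)
}

#' Static mother-level undesiredness classification
#'
#' Evaluates the mother-level rules on living counts at survey time:
#' excess parity when living children `C_i` exceed the ideal family size
#' `C_m`; excess boys when living boys exceed `B_m + N_m`; excess girls
#' when living girls exceed `G_m + N_m`; dual excess per `dual_rule`
#' (`"both_sexes"`: both sex flags; `"sex_and_parity"`: a sex flag
#' together with the parity flag).
#'
#' @param pref a [fertility_pref].
#' @param sex character vector of child sexes (`"M"`/`"F"`), one per birth.
#' @param alive logical/0-1 vector, alive at survey.
#' @inheritParams classify_children_sequential
#' @return named integer vector with `excess_parity`, `excess_boys`,
#'   `excess_girls`, `excess_dual`.
#' @examples
#' classify_mother_static(fertility_pref(2, 1, 1),
#'                        sex = c("M", "M", "M", "F"),
#'                        alive = c(1, 1, 1, 1))
#' @export
classify_mother_static <- function(pref, sex, alive = rep(1, length(sex)),
                                   dual_rule = c("sex_and_parity",
                                                 "both_sexes")) {
  dual_rule <- match.arg(dual_rule)
  stopifnot(inherits(pref, "fertility_pref"), length(sex) == length(alive))
  live <- as.logical(alive)
  Bi <- sum(live & !is.na(sex) & sex == "M")
  Gi <- sum(live & !is.na(sex) & sex == "F")
  Ci <- sum(live)
  ep <- Ci - pref$C > 0
  eb <- Bi - (pref$B + pref$N) > 0
  eg <- Gi - (pref$G + pref$N) > 0
  dual <- switch(dual_rule,
                 both_sexes = eb && eg,
                 sex_and_parity = (eb || eg) && ep)
  c(excess_parity = as.integer(ep), excess_boys = as.integer(eb),
    excess_girls = as.integer(eg), excess_dual = as.integer(dual))
}

#' Vectorised sequential classification of a whole population
#'
#' Applies the same rules as [classify_children_sequential] to every
#' child in a population table, assuming the generator's event order:
#' births in birth order, with a death realised immediately after the
#' child's own birth (so a child who died never counts in the living
#' totals of later siblings).
#'
#' @param children data.frame/data.table with columns `mother_id`,
#'   `birth_order`, `sex` (`"M"`/`"F"`), `alive` (0/1).
#' @param mothers data.frame/data.table with columns `mother_id`, `B_m`,
#'   `G_m`, `N_m` (and optionally `C_m`).
#' @inheritParams classify_children_sequential
#' @return data.table: `mother_id`, `birth_order`, `sex`, and the five
#'   flag columns of [classify_children_sequential].
#' @export
classify_population <- function(mothers, children,
                                dual_rule = c("sex_and_parity",
                                              "both_sexes")) {
  dual_rule <- match.arg(dual_rule)
  ch <- data.table::as.data.table(children)
  mo <- data.table::as.data.table(mothers)
  need <- c("mother_id", "birth_order", "sex", "alive")
  if (length(miss <- setdiff(need, names(ch))))
    stopf("children table lacks column(s): %s", paste(miss, collapse = ", "))
  if (length(miss <- setdiff(c("mother_id", "B_m", "G_m", "N_m"), names(mo))))
    stopf("mothers table lacks column(s): %s", paste(miss, collapse = ", "))
  ch <- merge(ch[, need, with = FALSE],
              mo[, c("mother_id", "B_m", "G_m", "N_m"), with = FALSE],
              by = "mother_id", sort = FALSE)
  data.table::setorder(ch, mother_id, birth_order)
  # living same-sex counts just before each birth (immediate-death rule)
  male <- !is.na(ch$sex) & ch$sex == "M"
  female <- !is.na(ch$sex) & ch$sex == "F"
  lag0 <- function(x) data.table::shift(x, fill = 0L)
  ch[, `:=`(.ml = as.integer(male & alive == 1),
            .fl = as.integer(female & alive == 1),
            .al = as.integer(alive == 1))]
  ch[, `:=`(b_before = lag0(cumsum(.ml)),
            g_before = lag0(cumsum(.fl)),
            n_before = lag0(cumsum(.al))), by = "mother_id"]
  ch[, c(".ml", ".fl", ".al") := NULL]
  Nm <- ch$N_m
  own  <- ifelse(male, ch$b_before + 1L, ch$g_before + 1L)
  ownq <- ifelse(male, ch$B_m, ch$G_m)
  oth  <- ifelse(male, ch$g_before, ch$b_before)
  othq <- ifelse(male, ch$G_m, ch$B_m)
  consumed <- pmin(pmax(0L, oth - othq), Nm)
  eg <- (own > ownq + (Nm - consumed)) & (male | female)
  ep <- ch$n_before + 1L > ch$B_m + ch$G_m + Nm
  ch[, `:=`(excess_gender = as.integer(eg), excess_parity = as.integer(ep))]
  if (dual_rule == "sex_and_parity") {
    ch[, excess_dual := as.integer(excess_gender == 1L & excess_parity == 1L)]
  } else {
    ch[, `:=`(.male = male, .female = female)]
    ch[, excess_dual := {
      heb <- any(excess_gender == 1L & .male)
      heg <- any(excess_gender == 1L & .female)
      as.integer(excess_gender == 1L & ((.male & heg) | (.female & heb)))
    }, by = "mother_id"]
    ch[, c(".male", ".female") := NULL]
  }
  ch[, `:=`(excess_boys = as.integer(excess_gender == 1L & male),
            excess_girls = as.integer(excess_gender == 1L & female))]
  ch[, c("B_m", "G_m", "N_m", "b_before", "g_before", "n_before") := NULL]
  ch[]
}

#' Prevalence of the four undesiredness categories
#'
#' Child-level prevalence (percent of children flagged) and mother-level
#' prevalence (percent of mothers with at least one flagged child) for
#' excess boys, excess girls, excess parity and dual excess.
#'
#' @param flags output of [classify_population] (or compatible table
#'   with `mother_id` and the four category columns).
#' @param n_mothers optional total number of mothers (defaults to the
#'   number of distinct `mother_id`s in `flags`; pass the population
#'   total when childless mothers exist).
#' @return list with data.tables `child` and `mother`
#'   (`category`, `n_flagged`, `n_total`, `percent`).
#' @export
aggregate_excess <- function(flags, n_mothers = NULL) {
  fl <- data.table::as.data.table(flags)
  cats <- c("excess_boys", "excess_girls", "excess_parity", "excess_dual")
  if (length(miss <- setdiff(c("mother_id", cats), names(fl))))
    stopf("flags table lacks column(s): %s", paste(miss, collapse = ", "))
  n_ch <- nrow(fl)
  child <- data.table::data.table(
    category = cats,
    n_flagged = vapply(cats, function(cc) sum(fl[[cc]]), numeric(1)),
    n_total = n_ch)
  child[, percent := ifelse(n_total > 0, 100 * n_flagged / n_total, 0)]
  bym <- fl[, lapply(.SD, function(x) as.integer(any(x == 1L))),
            by = "mother_id", .SDcols = cats]
  n_mo <- max(n_mothers %||% nrow(bym), nrow(bym))
  mother <- data.table::data.table(
    category = cats,
    n_flagged = vapply(cats, function(cc) sum(bym[[cc]]), numeric(1)),
    n_total = n_mo)
  mother[, percent := ifelse(n_total > 0, 100 * n_flagged / n_total, 0)]
  list(child = child[], mother = mother[])
}

#' Eligibility filtering of survey tables
#'
#' Applies the inclusion rules before any analysis: mothers with missing
#' or non-numeric ideal-composition answers are dropped, mothers with an
#' ideal family size above nine are dropped (with their children), and -
#' when a child age column is available - the child-level outcome tables
#' are restricted to children born in the five years before the survey
#' (`age_ch` 0-4).
#'
#' @param mothers,children population tables (see [classify_population]).
#' @param max_ideal eligibility cap on `C_m` (default 9).
#' @return list with `mothers`, `children` (filtered data.tables) and
#'   `report`, a data.table of per-rule drop counts.
#' @export
apply_eligibility_filters <- function(mothers, children, max_ideal = 9) {
  mo <- data.table::as.data.table(mothers)
  ch <- data.table::as.data.table(children)
  for (col in c("mother_id", "B_m", "G_m", "N_m"))
    if (!col %in% names(mo)) stopf("mothers table lacks column '%s'", col)
  for (col in c("mother_id", "birth_order", "sex", "alive"))
    if (!col %in% names(ch)) stopf("children table lacks column '%s'", col)
  n0 <- nrow(mo)
  ideal <- suppressWarnings(
    as.numeric(mo$B_m) + as.numeric(mo$G_m) + as.numeric(mo$N_m))
  bad_na <- is.na(ideal)
  bad_cap <- !bad_na & ideal > max_ideal
  mo_keep <- mo[!(bad_na | bad_cap)]
  orphan <- !(ch$mother_id %in% mo_keep$mother_id)
  ch_keep <- ch[!orphan]
  n_ch0 <- nrow(ch_keep)
  if ("age_ch" %in% names(ch_keep)) {
    over5 <- is.na(ch_keep$age_ch) | ch_keep$age_ch > 4
    ch_keep <- ch_keep[!over5]
  } else over5 <- logical(0)
  report <- data.table::data.table(
    rule = c("ideal_missing", "ideal>9", "child_of_dropped_mother",
             "child_age_over_5", "mothers_retained", "children_retained"),
    n = c(sum(bad_na), sum(bad_cap), sum(orphan), sum(over5),
          nrow(mo_keep), nrow(ch_keep)))
  list(mothers = mo_keep[], children = ch_keep[], report = report)
}
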