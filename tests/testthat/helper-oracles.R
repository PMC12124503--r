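# Independent slot-consumption simulator for the sequential classifier.
# At every birth it re-assigns ALL living children (in birth order) to
# sex-specific slots first, then either-gender slots; the newborn is
# gender-excess iff no slot is left for it, parity-excess iff the living
# count including it exceeds the ideal family size.  Deliberately a
# different code path from the package's arithmetic rule.
oracle_classify <- function(pref, events) {
  if (is.character(events)) {
    ev <- lapply(events, function(e) {
      if (e %in% c("B", "G"))
        list(type = "birth", sex = if (e == "B") "M" else "F")
      else list(type = "death", child = as.integer(sub("^D", "", e)))
    })
  } else {
    ev <- lapply(seq_len(nrow(events)), function(i)
      if (events$event[i] == "birth")
        list(type = "birth", sex = events$sex[i])
      else list(type = "death", child = events$child[i]))
  }
  sex <- character(0); alive <- logical(0)
  gflag <- pflag <- integer(0)
  assign_slots <- function(sexes) {
    # returns logical: got a slot?  iterate in birth order
    nb <- pref$B; ng <- pref$G; ne <- pref$N
    got <- logical(length(sexes))
    for (i in seq_along(sexes)) {
      s <- sexes[i]
      if (is.na(s)) { got[i] <- TRUE; next }
      if (s == "M") {
        if (nb > 0) { nb <- nb - 1; got[i] <- TRUE }
        else if (ne > 0) { ne <- ne - 1; got[i] <- TRUE }
      } else {
        if (ng > 0) { ng <- ng - 1; got[i] <- TRUE }
        else if (ne > 0) { ne <- ne - 1; got[i] <- TRUE }
      }
    }
    got
  }
  for (e in ev) {
    if (e$type == "birth") {
      sex <- c(sex, e$sex); alive <- c(alive, TRUE)
      got <- assign_slots(sex[alive])
      gflag <- c(gflag, as.integer(!got[length(got)]))
      pflag <- c(pflag, as.integer(sum(alive) > pref$C))
    } else {
      alive[e$child] <- FALSE
    }
  }
  data.frame(birth_order = seq_along(sex), sex = sex,
             excess_gender = gflag, excess_parity = pflag,
             excess_dual = as.integer(gflag & pflag))
}

# all preference triples with ideal family size <= cmax
all_pref_triples <- function(cmax) {
  g <- expand.grid(B = 0:cmax, G = 0:cmax, N = 0:cmax)
  g[g$B + g$G + g$N <= cmax, ]
}

# all no-death birth sequences of length 1..len ("B"/"G")
all_birth_sequences <- function(len) {
  out <- list()
  for (k in seq_len(len)) {
    m <- as.matrix(expand.grid(rep(list(c("B", "G")), k),
                               stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  }
  out
}

# random event sequence with deaths of random living children
random_event_sequence <- function(max_events = 6) {
  ev <- character(0)
  alive <- integer(0)
  born <- 0L
  for (i in seq_len(sample.int(max_events, 1))) {
    if (length(alive) > 0 && runif(1) < 0.25) {
      k <- alive[sample.int(length(alive), 1)]
      ev <- c(ev, paste0("D", k))
      alive <- setdiff(alive, k)
    } else {
      ev <- c(ev, sample(c("B", "G"), 1))
      born <- born + 1L
      alive <- c(alive, born)
    }
  }
  ev
}

# two well-separated Gaussian blobs: linearly separable by construction
make_blobs <- function(n = 600, p_noise = 2, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  d <- data.frame(y = y,
                  f1 = rnorm(n, mean = sep * y),
                  f2 = rnorm(n, mean = -sep * y))
  for (j in seq_len(p_noise)) d[[paste0("noise", j)]] <- rnorm(n)
  d
}

# small deterministic mothers/children fixture
toy_population <- function() {
  mothers <- data.frame(
    mother_id = 1:3,
    B_m = c(2L, 0L, 1L), G_m = c(1L, 0L, 1L), N_m = c(1L, 0L, 0L),
    C_m = c(4L, 0L, 2L))
  children <- data.frame(
    mother_id = c(1, 1, 1, 1, 1, 1, 2, 3),
    birth_order = c(1, 2, 3, 4, 5, 6, 1, 1),
    sex = c("M", "M", "M", "M", "F", "M", "F", "M"),
    alive = c(1, 1, 0, 1, 1, 1, 1, 1))
  list(mothers = mothers, children = children)
}
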