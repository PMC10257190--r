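# Phase-I training loop: plan every training molecule with the current
# network, harvest every reaction node's (molecule, template, q_bar) as
# experience -- failed and unproven decompositions included, which is the
# point of the method -- deduplicate repeated actions to their mean score,
# retrain the network for a fixed number of epochs, and validate on a
# held-out molecule set. The loop continues while validation keeps
# improving on the best of the last five rounds (success rate by more than
# eps1, or average iterations by more than eps2) and stops otherwise.

#' Collect experience records from a finished search tree
#'
#' One record per reaction node: the parent molecule, the template, and the
#' node's current q_bar. Proven, disproven and still-open nodes are all
#' included; scores of unproven decompositions carry exactly the signal the
#' guidance network is meant to learn.
#'
#' @param tree A finished `search_tree`.
#' @return data.frame with columns `molecule`, `template`, `label`
#'   (raw q_bar, reward scale), `occurrences` (all 1).
#' @export
collect_experience <- function(tree) {
  nodes <- tree_nodes(tree)
  rxn <- Filter(function(n) n$kind == "rxn", nodes)
  data.frame(
    molecule = vapply(rxn, function(n) n$parent$molecule, character(1)),
    template = vapply(rxn, function(n) n$template, character(1)),
    label = vapply(rxn, function(n) n$q_bar, numeric(1)),
    occurrences = rep(1L, length(rxn)),
    stringsAsFactors = FALSE
  )
}

#' Deduplicate experience records
#'
#' The same decomposition action (molecule, template) can occur in many
#' trees (and at several places in one tree); duplicates are unified to a
#' single record whose label is the arithmetic mean of all occurrences.
#' Order-insensitive: any permutation of the input yields the same output.
#'
#' @param records data.frame as returned by [collect_experience()]
#'   (possibly row-bound across trees).
#' @return Deduplicated data.frame, sorted by molecule then template, with
#'   `occurrences` counting the merged rows.
#' @export
dedup_experience <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$molecule, records$template, sep = "\r")
  lab <- tapply(records$label * records$occurrences, key, sum) /
    tapply(records$occurrences, key, sum)
  occ <- tapply(records$occurrences, key, sum)
  ks <- sort(names(lab))
  parts <- strsplit(ks, "\r", fixed = TRUE)
  data.frame(
    molecule = vapply(parts, `[`, character(1), 1L),
    template = vapply(parts, `[`, character(1), 2L),
    label = as.numeric(lab[ks]),
    occurrences = as.integer(occ[ks]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Build a training design from experience records
#'
#' Featurizes each (molecule, template) pair and maps reward-scale labels
#' into the network's \eqn{[0, 1]} range with [squash_label()].
#'
#' @param records Deduplicated experience data.frame.
#' @param z Reward magnitude used during collection.
#' @param nbits Fingerprint width per half.
#' @return List with sparse matrix `x` and numeric vector `y`.
#' @export
experience_design <- function(records, z = 10, nbits = 2048L) {
  list(
    x = .pair_matrix(records$molecule, records$template, nbits),
    y = squash_label(records$label, z)
  )
}

#' Phase-I stopping rule
#'
#' Continue training (`TRUE`) iff the current round improves on the best
#' of the last (up to) five completed rounds: success-rate gain above
#' `eps1`, or average-iteration drop above `eps2`. With an empty history
#' the round trivially counts as an improvement and the loop continues.
#'
#' @param history data.frame with columns `R_s` and `R_a`, one row per
#'   completed validation round (most recent last); only the last five rows
#'   are consulted.
#' @param rs_i Success rate of the current round.
#' @param ra_i Average iteration count of the current round.
#' @param eps1 Success-rate improvement threshold.
#' @param eps2 Average-iteration improvement threshold.
#' @return Logical: `TRUE` to continue, `FALSE` to stop.
#' @export
loop_condition <- function(history, rs_i, ra_i, eps1 = 0.015, eps2 = 3) {
  if (is.null(history) || nrow(history) == 0L) return(TRUE)
  recent <- history[max(1L, nrow(history) - 4L):nrow(history), , drop = FALSE]
  rs_max <- max(recent$R_s)
  ra_min <- min(recent$R_a)
  (rs_i - rs_max > eps1) || (ra_min - ra_i > eps2)
}

#' Train an experience guidance network by self-play
#'
#' Runs the Phase-I loop: in round i, plan every training molecule with
#' the round-(i-1) network, pool and deduplicate the experience, train the
#' network for `epochs` epochs, then validate by planning every validation
#' molecule and recording the success rate and the average number of
#' iterations (failures charged the full budget). At least one round is
#' completed; afterwards the loop continues only while [loop_condition()]
#' holds, up to `rounds_max` rounds. The returned network is the round
#' with the best validation performance (highest success rate, ties broken
#' by fewer average iterations).
#'
#' @param train_molecules,val_molecules Non-empty character vectors of
#'   molecule ids.
#' @param model Single-step model (e.g. a `reaction_universe`).
#' @param config `planner_config` used for both training and validation
#'   plans (training plans run in multi-route mode so that trees keep
#'   accumulating experience after a first route is found; set
#'   `train_stop_on_proven = TRUE` to override).
#' @param epochs Training epochs per round.
#' @param eps1,eps2 Stopping-rule thresholds.
#' @param rounds_max Hard cap on training rounds.
#' @param dropout_rate Hidden-layer dropout during training.
#' @param baseline If `TRUE` (default), first evaluate the non-learning
#'   planner (all Q0 = 0.5) on the validation set and record it as round
#'   0. The baseline row seeds the stopping window, so a first round that
#'   fails to improve on the unguided planner ends the loop immediately;
#'   with `baseline = FALSE` the first round always continues (there is
#'   nothing to compare against).
#' @param train_stop_on_proven Stop training plans at the first route.
#' @param seed Master seed; all per-molecule planning seeds, weight
#'   initialization and training shuffles derive from it.
#' @return List of class `phase1_result`: `egn` (best parameters),
#'   `history` (per-round data.frame of `round`, `R_s`, `R_a`,
#'   `n_records`), `best_round`.
#' @export
train_egn_loop <- function(train_molecules, val_molecules, model,
                           config = planner_config(),
                           epochs = 20L, eps1 = 0.015, eps2 = 3,
                           rounds_max = 20L, dropout_rate = 0.1,
                           baseline = TRUE, train_stop_on_proven = FALSE,
                           seed = 1L) {
  if (length(train_molecules) == 0L || length(val_molecules) == 0L) {
    stop_egmcts("argument", "training and validation sets must be non-empty")
  }
  egn <- egn_init(dropout_rate = dropout_rate, seed = seed %% 2^31)
  history <- data.frame(round = integer(0), R_s = numeric(0), R_a = numeric(0),
                        n_records = integer(0))
  evaluate <- function(params, round_i) {
    solved <- logical(length(val_molecules))
    iters <- numeric(length(val_molecules))
    for (j in seq_along(val_molecules)) {
      cfg <- config
      cfg$seed <- as.integer((config$seed + 7919 * round_i + j) %% 2^31)
      cfg$stop_on_proven <- TRUE
      tr <- plan(val_molecules[j], model, params, cfg)
      solved[j] <- tr$root$status == "proven"
      iters[j] <- if (solved[j]) tr$iterations_used else config$iter_limit
    }
    c(R_s = mean(solved), R_a = mean(iters))
  }

  if (baseline) {
    b <- evaluate(NULL, 0L)
    history <- rbind(history, data.frame(
      round = 0L, R_s = b[["R_s"]], R_a = b[["R_a"]], n_records = 0L
    ))
  }

  best <- NULL
  best_round <- NA_integer_
  for (i in seq_len(rounds_max)) {
    pool <- vector("list", length(train_molecules))
    for (j in seq_along(train_molecules)) {
      cfg <- config
      cfg$seed <- as.integer((config$seed + 104729 * i + 31 * j) %% 2^31)
      cfg$stop_on_proven <- train_stop_on_proven
      tr <- plan(train_molecules[j], model, egn, cfg)
      pool[[j]] <- collect_experience(tr)
    }
    records <- dedup_experience(do.call(rbind, pool))
    if (nrow(records) > 0L) {
      design <- experience_design(records, z = config$z,
                                  nbits = egn$input_dim %/% 2L)
      egn <- egn_train(egn, design$x, design$y, epochs = epochs,
                       seed = as.integer((seed + 15485863 * i) %% 2^31))
    }
    v <- evaluate(egn, i)
    go_on <- loop_condition(history, v[["R_s"]], v[["R_a"]], eps1, eps2)
    history <- rbind(history, data.frame(
      round = i, R_s = v[["R_s"]], R_a = v[["R_a"]], n_records = nrow(records)
    ))
    if (is.null(best) || v[["R_s"]] > best$R_s ||
        (v[["R_s"]] == best$R_s && v[["R_a"]] < best$R_a)) {
      best <- list(egn = egn, R_s = v[["R_s"]], R_a = v[["R_a"]])
      best_round <- i
    }
    if (!go_on) break
  }
  structure(
    list(egn = best$egn, history = history, best_round = best_round),
    class = "phase1_result"
  )
}

#' @export
print.phase1_result <- function(x, ...) {
  cat(sprintf("<phase1_result> %d round(s), best round %d\n",
              sum(x$history$round > 0), x$best_round))
  print(x$history, row.names = FALSE)
  invisible(x)
}
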