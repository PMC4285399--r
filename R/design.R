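#' Temperature levels used in the thermal stimulation task
#'
#' Level 1 is 44.3 degC and each level adds 1 degC, up to level 6 (49.3 degC).
#' @keywords internal
TEMP_LEVELS_C <- 44.3 + 0:5

#' Generate counterbalanced experimental designs
#'
#' Builds per-subject trial tables for the nine-run thermal pain task:
#' five counterbalanced "passive experience" runs (runs 1, 2, 4, 8, 9) of 11
#' trials each over temperature levels 1-5, in which every ordered pair of
#' levels occurs as a within-run transition exactly twice and the five runs
#' start with five distinct levels (runs 2 and 8 always start with levels 4
#' and 2); two shifted-context passive runs (runs 5 and 6) that repeat the
#' sequences of runs 4 and 8 with every level raised by one (levels 2-6); and
#' two regulation runs (runs 3 and 7) of 10 trials, two per level 1-5, with
#' an identical stimulus order in both. The order of the regulate-up and
#' regulate-down runs alternates across subjects (odd-numbered subjects
#' regulate up first).
#'
#' The transition counterbalancing is solved by decomposing the 50-edge
#' directed multigraph holding two copies of every ordered level pair
#' (self-transitions included) into five 10-edge trails with the mandated
#' distinct start levels: a random Eulerian circuit of the multigraph is cut
#' at five equally spaced points, and circuits are redrawn until some
#' rotation of the cut yields start nodes that are a permutation of 1..5.
#'
#' @param n_subjects number of subjects to generate (>= 1).
#' @param seed integer seed; the design is fully reproducible from it.
#' @param max_attempts circuits to try per subject before giving up.
#' @return A data frame with one row per trial and columns `subject`, `run`,
#'   `run_type` (`"passive"`, `"regulate_up"`, `"regulate_down"`),
#'   `trial_index`, `temp_level`, `temp_c`, `reg_code` (+1/0/-1),
#'   `reg_up_first` (+1/-1 subject-level covariate), and placeholder columns
#'   `rating`, `decision`, `excluded`, `vif`.
#' @export
generate_design <- function(n_subjects, seed, max_attempts = 500L) {
  stopifnot(n_subjects >= 1, is.numeric(seed))
  set.seed(as.integer(seed))
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    trails <- counterbalanced_trails(max_attempts)
    # trails is a list of five 11-node level sequences, names = start level
    starts <- vapply(trails, function(tr) tr[1L], integer(1))
    run_seq <- vector("list", 9L)
    run_seq[[2L]] <- trails[[which(starts == 4L)]]
    run_seq[[8L]] <- trails[[which(starts == 2L)]]
    odd_starts <- which(starts %in% c(1L, 3L, 5L))
    for149 <- sample(odd_starts) # random assignment of starts 1/3/5 to runs 1,4,9
    run_seq[[1L]] <- trails[[for149[1L]]]
    run_seq[[4L]] <- trails[[for149[2L]]]
    run_seq[[9L]] <- trails[[for149[3L]]]
    # context runs repeat runs 4 and 8 one level higher (levels 2-6)
    run_seq[[5L]] <- run_seq[[4L]] + 1L
    run_seq[[6L]] <- run_seq[[8L]] + 1L
    # regulation runs: ten trials, two per level 1-5, same order in both
    reg_order <- sample(rep(1:5, 2L))
    run_seq[[3L]] <- reg_order
    run_seq[[7L]] <- reg_order
    up_first <- (s %% 2L) == 1L
    run_type <- rep("passive", 9L)
    run_type[3L] <- if (up_first) "regulate_up" else "regulate_down"
    run_type[7L] <- if (up_first) "regulate_down" else "regulate_up"
    rows <- lapply(1:9, function(r) {
      lv <- run_seq[[r]]
      data.frame(
        subject = s, run = r, run_type = run_type[r],
        trial_index = seq_along(lv), temp_level = lv,
        temp_c = TEMP_LEVELS_C[lv],
        reg_code = switch(run_type[r], regulate_up = 1L,
                          regulate_down = -1L, passive = 0L),
        reg_up_first = if (up_first) 1L else -1L,
        stringsAsFactors = FALSE
      )
    })
    out[[s]] <- do.call(rbind, rows)
  }
  design <- do.call(rbind, out)
  design$rating <- NA_real_
  design$decision <- NA_integer_
  design$excluded <- FALSE
  design$vif <- NA_real_
  rownames(design) <- NULL
  design
}

# Decompose two copies of every ordered pair over levels 1..5 into five
# 10-edge trails whose start nodes are exactly {1,...,5}.
counterbalanced_trails <- function(max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    circ <- random_eulerian_circuit_5()    # 50 nodes, circular
    for (p in sample.int(50L) - 1L) {
      cut_idx <- (p + c(0L, 10L, 20L, 30L, 40L)) %% 50L + 1L
      starts <- circ[cut_idx]
      if (length(unique(starts)) == 5L) {
        trails <- lapply(0:4, function(k) {
          idx <- (p + 10L * k + 0:10) %% 50L + 1L
          circ[idx]
        })
        return(trails)
      }
    }
  }
  stop("counterbalancing construction failed after ", max_attempts,
       " attempts; constraints appear infeasible")
}

# Random Eulerian circuit of the complete directed multigraph on 5 nodes
# with every ordered pair (self-loops included) duplicated: 50 edges,
# in-degree = out-degree = 10 at every node. Hierholzer's algorithm with
# randomized edge order; returns the 50 visited nodes (circular order).
random_eulerian_circuit_5 <- function() {
  adj <- lapply(1:5, function(v) sample(rep(1:5, 2L)))
  nxt <- rep(1L, 5L)
  stack <- integer(51L); stack[1L] <- 1L; top <- 1L
  circuit <- integer(51L); ci <- 0L
  while (top > 0L) {
    v <- stack[top]
    if (nxt[v] <= 10L) {
      u <- adj[[v]][nxt[v]]
      nxt[v] <- nxt[v] + 1L
      top <- top + 1L
      stack[top] <- u
    } else {
      ci <- ci + 1L
      circuit[ci] <- v
      top <- top - 1L
    }
  }
  rev(circuit)[1:50] # drop the repeated final node
}

#' Tabulate within-run temperature transitions
#'
#' Counts ordered `from -> to` level transitions inside each of the given
#' runs (never across run boundaries) for one subject's design.
#'
#' @param design a trial table as returned by [generate_design()].
#' @param subject subject id.
#' @param runs which runs to count over (default: the five counterbalanced
#'   passive runs).
#' @return a 5 x 5 matrix of transition counts over levels 1-5.
#' @export
transition_table <- function(design, subject, runs = c(1, 2, 4, 8, 9)) {
  tab <- matrix(0L, 5L, 5L, dimnames = list(from = 1:5, to = 1:5))
  for (r in runs) {
    lv <- design$temp_level[design$subject == subject & design$run == r]
    if (length(lv) < 2L) next
    for (i in seq_len(length(lv) - 1L)) {
      tab[lv[i], lv[i + 1L]] <- tab[lv[i], lv[i + 1L]] + 1L
    }
  }
  tab
}
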