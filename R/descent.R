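#' @name descent
#' @title Coordinate descent over mixtures and integer copy numbers
#'
#' @description
#' The full objective is non-linear in `(U, C)` jointly, so it is minimized
#' by alternating two linear programs: a continuous U-step (mixture
#' fractions on the probability simplex, with `C` fixed) and an integer
#' C-step (clonal copy numbers, tree, RNA mapping, gain placements, with
#' `U` fixed). The C-step runs either in one joint ILP or in the default
#' two-stage form: first segments + tree + RNA mapping, then SNV/SV columns
#' with the tree and segments held fixed. Multiple random restarts guard
#' against local minima; the restart with the lowest final objective wins,
#' ties broken by restart index.
NULL

#' Run configuration for the coordinate descent
#'
#' @param iterations coordinate-descent iterations per restart
#' @param restarts number of random restarts
#' @param time_limit wall-clock seconds per C-step iteration (split equally
#'   across the two stages in two-stage mode); `NULL` for no limit
#' @param seed base RNG seed; restart `q` uses `seed + q - 1`
#' @param mode `"two_stage"` (default) or `"joint"` C-step
#' @param ratio_snvs include SNVs in the ratio regularizer
#' @param ratio_in_ustep include the U-dependent ratio term in the U-step
#'   objective (keeps the descent monotone on the shared objective); set
#'   `FALSE` to restrict the U-step to the deconvolution fit alone
#' @param early_stop_tol stop a restart early when the objective improves by
#'   less than this between iterations (`NULL` disables)
#' @return a list of class `run_config`
#' @export
run_config <- function(iterations = 3L, restarts = 3L, time_limit = NULL,
                       seed = 1L, mode = c("two_stage", "joint"),
                       ratio_snvs = TRUE, ratio_in_ustep = TRUE,
                       early_stop_tol = NULL) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 1, restarts >= 1,
            is.null(time_limit) || time_limit > 0)
  structure(list(iterations = as.integer(iterations),
                 restarts = as.integer(restarts),
                 time_limit = time_limit, seed = as.integer(seed),
                 mode = mode, ratio_snvs = ratio_snvs,
                 ratio_in_ustep = ratio_in_ustep,
                 early_stop_tol = early_stop_tol),
            class = "run_config")
}

#' Default regularization weights
#'
#' `lambda1` scales the phylogenetic cost to the size of the deconvolution
#' fit term: half the ratio of the fit term's entry count, `(l+g+2r) * m`,
#' to the phylogenetic cost's, roughly `2r` per edge times `N` edges-or-
#' nodes. `lambda2` is half the ratio of total variant columns to mutation
#' columns.
#'
#' @param l,g,r breakend, SNV and segment counts
#' @param m sample count
#' @param n clone count
#' @param edges use `n - 1` (edge count) instead of `n` for `N`
#' @return list with `lambda1` and `lambda2`
#' @export
compute_lambdas <- function(l, g, r, m, n, edges = FALSE) {
  if (l + g == 0) stop("l + g = 0: no mutations to place, lambda2 undefined")
  stopifnot(r > 0, m > 0, n > 0)
  N <- if (edges) n - 1 else n
  list(lambda1 = 0.5 * ((l + g + 2 * r) * m) / (2 * r * N),
       lambda2 = 0.5 * (l + g + 2 * r) / (l + g))
}

#' Random mixture initialization
#'
#' Rows are drawn from a flat Dirichlet (all concentrations 1), so every
#' point of the simplex is equally likely; reproducible per seed.
#'
#' @param m,n dimensions
#' @param seed RNG seed
#' @return an `m x n` matrix with nonnegative rows summing to 1
#' @export
init_U <- function(m, n, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  U <- matrix(stats::rgamma(m * n, shape = 1), nrow = m)
  U / rowSums(U)
}

#' U-step: optimal mixture fractions for a fixed copy-number matrix
#'
#' Solves the continuous LP minimizing `|F - UC|` (plus, by default, the
#' U-dependent ratio regularizer `lambda2 * S`) subject to `U >= 0` and
#' unit row sums.
#'
#' @param instance a [problem_instance()]
#' @param C fixed clonal copy-number matrix
#' @param ratio_snvs,ratio_in_ustep see [run_config()]
#' @param time_limit seconds, `NULL` for none
#' @return the optimal `m x n` mixture matrix
#' @export
solve_U <- function(instance, C, ratio_snvs = TRUE, ratio_in_ustep = TRUE,
                    time_limit = NULL) {
  idx <- instance$index
  m <- instance$m; n <- instance$n
  ncolF <- n_cols(idx)
  model <- milp_model()
  Uv <- milp_add_vars(model, "U", m * n, lb = 0, ub = 1)
  Fs <- milp_add_vars(model, "fslack", m * ncolF, lb = 0, ub = MILP_INF)
  u_idx <- function(i, k) Uv[(k - 1L) * m + i]
  f_idx <- function(i, j) Fs[(j - 1L) * m + i]
  rows <- list()
  for (i in seq_len(m)) {
    rows[[length(rows) + 1L]] <- list(idx = u_idx(i, seq_len(n)), coef = rep(1, n),
                                      lb = 1, ub = 1)
  }
  for (j in seq_len(ncolF)) {
    ccol <- C[, j]
    for (i in seq_len(m)) {
      uv <- u_idx(i, seq_len(n))
      rows[[length(rows) + 1L]] <- list(idx = c(f_idx(i, j), uv),
                                        coef = c(1, ccol), lb = instance$F[i, j])
      rows[[length(rows) + 1L]] <- list(idx = c(f_idx(i, j), uv),
                                        coef = c(1, -ccol), lb = -instance$F[i, j])
    }
  }
  milp_set_obj(model, Fs, rep(1, length(Fs)))
  rcols <- if (ratio_snvs) mutation_cols(idx) else breakpoint_cols(idx)
  if (ratio_in_ustep && length(rcols)) {
    # S is linear in U with C fixed: per (i, b) the deviation is
    # sum_k U[i,k] * (C[k,b] - pi[i,b] * (C[k,seg1] + C[k,seg2]))
    pi_mat <- observed_ratios(instance$F, idx)
    seg_of <- apply(idx$Q, 1L, which.max)
    s1 <- segment_cols(idx, "1"); s2 <- segment_cols(idx, "2")
    Sv <- milp_add_vars(model, "sslack", m * length(rcols), lb = 0, ub = MILP_INF)
    s_idx <- function(i, bpos) Sv[(bpos - 1L) * m + i]
    for (bpos in seq_along(rcols)) {
      b <- rcols[bpos]
      segsum <- C[, s1[seg_of[b]]] + C[, s2[seg_of[b]]]
      for (i in seq_len(m)) {
        coefv <- C[, b] - pi_mat[i, b] * segsum
        uv <- u_idx(i, seq_len(n))
        rows[[length(rows) + 1L]] <- list(idx = c(s_idx(i, bpos), uv),
                                          coef = c(1, -coefv), lb = 0)
        rows[[length(rows) + 1L]] <- list(idx = c(s_idx(i, bpos), uv),
                                          coef = c(1, coefv), lb = 0)
      }
    }
    milp_set_obj(model, Sv, rep(instance$lambda2, length(Sv)))
  }
  milp_add_constrs(model, rows)
  res <- milp_solve(model, time_limit = time_limit)
  if (is.null(res$x)) stop("U-step LP failed: ", res$status)
  U <- milp_block(model, res$x, "U", dim = c(m, n))
  # clean tiny LP noise and renormalize exactly
  U[U < 0] <- 0
  U / rowSums(U)
}

#' C-step: copy numbers, tree, RNA mapping and gain placements for fixed U
#'
#' @param instance a [problem_instance()]
#' @param U fixed mixture matrix
#' @param config a [run_config()]
#' @return a list as returned by [solve_cstep()]; in two-stage mode the
#'   second-stage result with the first-stage tree and segments pinned
#' @export
solve_C <- function(instance, U, config = run_config()) {
  tl <- config$time_limit
  if (config$mode == "joint") {
    cm <- build_cstep_model(instance, U, mode = "joint",
                            ratio_snvs = config$ratio_snvs)
    return(solve_cstep(cm, time_limit = tl))
  }
  stage_tl <- if (is.null(tl)) NULL else tl / 2
  cm1 <- build_cstep_model(instance, U, mode = "segment")
  s1 <- solve_cstep(cm1, time_limit = stage_tl)
  cm2 <- build_cstep_model(instance, U, mode = "joint",
                           ratio_snvs = config$ratio_snvs)
  fix_stage1(cm2, list(E = s1$E, A = s1$A, M = s1$M, C_seg = s1$C_prime))
  s2 <- solve_cstep(cm2, time_limit = stage_tl)
  s2$stage1_status <- s1$status
  s2
}

#' Run the full coordinate descent
#'
#' For each restart: draw a random `U`, then alternate [solve_C()] and
#' [solve_U()] for the configured number of iterations, recording the four
#' objective terms after every iteration. Returns the best solution across
#' restarts (lowest total objective, ties to the lowest restart index) with
#' the full iteration log attached.
#'
#' @param instance a validated [problem_instance()]
#' @param config a [run_config()]
#' @return a [clone_solution()] with attributes `log` (per-iteration term
#'   data.frame) and `config`
#' @export
run_deconvolution <- function(instance, config = run_config()) {
  violations <- validate_instance(instance)
  if (length(violations)) {
    stop("invalid instance:\n  ", paste(violations, collapse = "\n  "))
  }
  best <- NULL
  best_obj <- Inf
  log_rows <- list()
  failures <- character(0)
  for (q in seq_len(config$restarts)) {
    restart_seed <- config$seed + q - 1L
    sol <- tryCatch(
      run_one_restart(instance, config, restart_seed, q, log_rows_out = function(row) {
        log_rows[[length(log_rows) + 1L]] <<- row
      }),
      error = function(e) {
        failures <<- c(failures, sprintf("restart %d: %s", q, conditionMessage(e)))
        NULL
      })
    if (!is.null(sol) && sol$objective_terms$total < best_obj - 1e-12) {
      best <- sol
      best_obj <- sol$objective_terms$total
    }
  }
  if (is.null(best)) {
    stop("all restarts failed:\n  ", paste(failures, collapse = "\n  "))
  }
  attr(best, "log") <- do.call(rbind, log_rows)
  attr(best, "config") <- config
  attr(best, "failures") <- failures
  best
}

run_one_restart <- function(instance, config, restart_seed, restart_id,
                            log_rows_out) {
  U <- init_U(instance$m, instance$n, seed = restart_seed)
  sol_c <- NULL
  prev_total <- Inf
  for (it in seq_len(config$iterations)) {
    sol_c <- solve_C(instance, U, config)
    U <- solve_U(instance, sol_c$C, ratio_snvs = config$ratio_snvs,
                 ratio_in_ustep = config$ratio_in_ustep,
                 time_limit = config$time_limit)
    terms <- evaluate_objective(instance, U, sol_c$C, sol_c$E, sol_c$M,
                                ratio_snvs = config$ratio_snvs)
    log_rows_out(data.frame(
      restart = restart_id, iteration = it, seed = restart_seed,
      fit = terms$fit, rna = terms$rna, phylo = terms$phylo,
      ratio = terms$ratio, total = terms$total,
      cstep_status = sol_c$status,
      mip_gap = ifelse(is.na(sol_c$mip_gap), NA_real_, sol_c$mip_gap)
    ))
    if (!is.null(config$early_stop_tol) &&
        prev_total - terms$total < config$early_stop_tol) break
    prev_total <- terms$total
  }
  terms <- evaluate_objective(instance, U, sol_c$C, sol_c$E, sol_c$M,
                              ratio_snvs = config$ratio_snvs)
  tree <- clone_tree(sol_c$E, A = sol_c$A)
  nm <- instance$index$l + instance$index$g
  W <- if (is.null(sol_c$W)) array(0, dim = c(instance$n, instance$n, nm)) else sol_c$W
  D <- if (is.null(sol_c$D)) numeric(nm) else sol_c$D
  sol <- clone_solution(U = U, C = sol_c$C, C_prime = sol_c$C_prime,
                        M = sol_c$M, tree = tree, W = W, D = D,
                        objective_terms = terms)
  bad <- validate_solution(sol, instance)
  if (length(bad)) {
    stop("extracted solution violates invariants:\n  ",
         paste(bad, collapse = "\n  "))
  }
  sol
}
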