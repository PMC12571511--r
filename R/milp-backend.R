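#' @name milp-backend
#' @title Mixed-integer linear programming backend
#'
#' @description
#' A minimal declarative model builder plus a solver bridge. Models are
#' assembled as sparse constraint triplets over named variable blocks and
#' solved with HiGHS through a bundled SciPy bridge script executed as a
#' subprocess (single-threaded and deterministic; relative MIP gap 0, wall
#' clock limit supported). The builder is intentionally small: every
#' constraint is linear, every variable bound finite.
NULL

MILP_INF <- 1e30

#' Create an empty MILP model
#'
#' @return an environment of class `milp_model` accumulating variables,
#'   constraint triplets and objective coefficients.
#' @keywords internal
milp_model <- function() {
  m <- new.env(parent = emptyenv())
  m$nvar <- 0L
  m$lb <- numeric(0)
  m$ub <- numeric(0)
  m$integrality <- integer(0)
  m$obj <- numeric(0)
  m$blocks <- list()
  # constraint triplets, grown in chunks
  m$con_i <- integer(0)
  m$con_j <- integer(0)
  m$con_x <- numeric(0)
  m$row_lb <- numeric(0)
  m$row_ub <- numeric(0)
  class(m) <- "milp_model"
  m
}

#' Add a block of decision variables
#'
#' @param model a `milp_model`
#' @param name block name (must be unique within the model)
#' @param n number of variables
#' @param lb,ub bounds, recycled to length `n`
#' @param type `"continuous"`, `"integer"` or `"binary"`
#' @return integer vector of the new variables' column indices
#' @keywords internal
milp_add_vars <- function(model, name, n, lb = 0, ub = MILP_INF,
                          type = c("continuous", "integer", "binary")) {
  type <- match.arg(type)
  stopifnot(n >= 0, is.null(model$blocks[[name]]))
  if (n == 0L) {
    model$blocks[[name]] <- integer(0)
    return(integer(0))
  }
  if (type == "binary") {
    lb <- pmax(rep_len(lb, n), 0)
    ub <- pmin(rep_len(ub, n), 1)
  }
  idx <- model$nvar + seq_len(n)
  model$nvar <- model$nvar + as.integer(n)
  model$lb <- c(model$lb, rep_len(lb, n))
  model$ub <- c(model$ub, rep_len(ub, n))
  model$integrality <- c(model$integrality,
                         rep_len(if (type == "continuous") 0L else 1L, n))
  model$obj <- c(model$obj, numeric(n))
  model$blocks[[name]] <- idx
  idx
}

#' Add one linear constraint lb <= sum(coef * x[idx]) <= ub
#' @keywords internal
milp_add_constr <- function(model, idx, coef, lb = -MILP_INF, ub = MILP_INF) {
  stopifnot(length(idx) == length(coef))
  row <- length(model$row_lb) + 1L
  model$con_i <- c(model$con_i, rep.int(row, length(idx)))
  model$con_j <- c(model$con_j, as.integer(idx))
  model$con_x <- c(model$con_x, as.numeric(coef))
  model$row_lb <- c(model$row_lb, lb)
  model$row_ub <- c(model$row_ub, ub)
  invisible(row)
}

#' Add many constraints at once from a triplet list
#'
#' `rows` is a list of lists with elements `idx`, `coef`, and optional
#' `lb`/`ub`. Faster than repeated [milp_add_constr()] for large blocks.
#' @keywords internal
milp_add_constrs <- function(model, rows) {
  if (!length(rows)) return(invisible(NULL))
  base <- length(model$row_lb)
  lens <- vapply(rows, function(r) length(r$idx), integer(1))
  model$con_i <- c(model$con_i, rep.int(base + seq_along(rows), lens))
  model$con_j <- c(model$con_j, as.integer(unlist(lapply(rows, `[[`, "idx"))))
  model$con_x <- c(model$con_x, as.numeric(unlist(lapply(rows, `[[`, "coef"))))
  model$row_lb <- c(model$row_lb, vapply(rows, function(r)
    if (is.null(r$lb)) -MILP_INF else r$lb, numeric(1)))
  model$row_ub <- c(model$row_ub, vapply(rows, function(r)
    if (is.null(r$ub)) MILP_INF else r$ub, numeric(1)))
  invisible(NULL)
}

#' Set objective coefficients (minimization)
#' @keywords internal
milp_set_obj <- function(model, idx, coef) {
  model$obj[idx] <- coef
  invisible(NULL)
}

#' Fix variables to given values via equal bounds
#' @keywords internal
milp_fix_vars <- function(model, idx, values) {
  stopifnot(length(idx) == length(values))
  model$lb[idx] <- values
  model$ub[idx] <- values
  invisible(NULL)
}

python_binary <- function() {
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (required by the MILP bridge)")
}

bridge_script <- function() {
  p <- system.file("python", "solve_milp.py", package = "clonedecon")
  if (!nzchar(p)) {
    # running from a source checkout (e.g. devtools::load_all)
    p <- file.path("inst", "python", "solve_milp.py")
  }
  if (!file.exists(p)) stop("MILP bridge script not found")
  p
}

#' Solve a MILP model
#'
#' @param model a `milp_model`
#' @param time_limit wall-clock limit in seconds, or `NULL` for none
#' @return a list with `x` (solution vector), `objective`, `status` string
#'   (`"optimal"`, `"time_limit"`, `"infeasible"`, `"unbounded"`, `"error"`),
#'   `mip_gap`, and `message`. `x` is `NULL` when no incumbent exists.
#' @keywords internal
milp_solve <- function(model, time_limit = NULL) {
  spec <- list(
    nvar = model$nvar,
    obj = model$obj,
    lb = model$lb,
    ub = model$ub,
    integrality = model$integrality,
    con_i = model$con_i,
    con_j = model$con_j,
    con_x = model$con_x,
    row_lb = model$row_lb,
    row_ub = model$row_ub,
    time_limit = time_limit
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(spec, fin, auto_unbox = TRUE, digits = NA, null = "null")
  code <- system2(python_binary(), c(shQuote(bridge_script()), shQuote(fin), shQuote(fout)),
                  stdout = FALSE, stderr = FALSE)
  if (code != 0L || !file.exists(fout)) {
    stop("MILP bridge failed with exit code ", code)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  status <- switch(as.character(res$status),
                   "0" = "optimal",
                   "1" = "time_limit",
                   "2" = "infeasible",
                   "3" = "unbounded",
                   "error")
  list(
    x = if (is.null(res$x)) NULL else as.numeric(res$x),
    objective = if (is.null(res$objective)) NA_real_ else as.numeric(res$objective),
    status = status,
    mip_gap = if (is.null(res$mip_gap)) NA_real_ else as.numeric(res$mip_gap),
    message = res$message
  )
}

#' Extract a named variable block from a solution vector
#' @keywords internal
milp_block <- function(model, solution_x, name, dim = NULL) {
  idx <- model$blocks[[name]]
  if (is.null(idx)) stop("unknown variable block: ", name)
  v <- solution_x[idx]
  if (!is.null(dim)) dim(v) <- dim
  v
}

#' Round near-integer solver values to exact integers
#' @keywords internal
round_integral <- function(v, tol = 1e-5) {
  r <- round(v)
  if (any(abs(v - r) > tol)) {
    warning("solver value deviates from integrality by more than ", tol)
  }
  r
}
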