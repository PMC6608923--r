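#' Build a SUTSE dynamic linear model specification
#'
#' Constructs the structural matrices of a seemingly-unrelated-time-series
#' (SUTSE) dynamic linear model in which each of `n_series` series carries a
#' local linear trend (level + slope, with innovation noise entering only the
#' slope, so the level is an integrated random walk) and `n_harmonics`
#' Fourier harmonics of a seasonal cycle of `period` steps.
#'
#' Per-series state coordinates are ordered
#' `(level, slope, harmonic_1, conjugate_1, ..., harmonic_q[, conjugate_q])`,
#' and series blocks are concatenated in input order.  When
#' `n_harmonics == period / 2` the final (Nyquist) harmonic degenerates to a
#' single alternating coordinate with transition \eqn{-1}, so each block has
#' `2 + 2q - 1` coordinates instead of `2 + 2q`.
#'
#' @param n_series number of parallel series \eqn{C} (positive integer).
#' @param n_harmonics number of seasonal harmonics \eqn{q}, between 0 and
#'   `period / 2`.
#' @param period seasonal period \eqn{s} (even positive integer; 12 for
#'   monthly data with an annual cycle).
#'
#' @return An object of class `sutse_model` with elements `n_series`,
#'   `n_harmonics`, `period`, `state_dim`, `obs_matrix` (\eqn{C \times p}
#'   matrix \eqn{F}), `transition` (\eqn{p \times p} matrix \eqn{G}),
#'   `evo_selection` (\eqn{p \times C} matrix mapping the slope disturbance
#'   \eqn{\tilde\delta_t} to the state disturbance
#'   \eqn{\delta_t = R \tilde\delta_t}), and `coord_labels` (a data frame of
#'   per-coordinate series index and role).
#'
#' @examples
#' m <- build_model(n_series = 6, n_harmonics = 0)
#' m$state_dim  # 12: one (level, slope) pair per series
#' build_model(6, 6)$state_dim  # 78: degenerate sixth harmonic
#' @export
build_model <- function(n_series, n_harmonics = 0L, period = 12L) {
  C <- n_series; q <- n_harmonics; s <- period
  if (length(C) != 1L || !is.finite(C) || C < 1 || C != round(C))
    stop_invalid_spec("n_series must be a positive integer")
  if (length(s) != 1L || !is.finite(s) || s < 2 || s != round(s) || s %% 2 != 0)
    stop_invalid_spec("period must be an even integer >= 2")
  if (length(q) != 1L || !is.finite(q) || q < 0 || q != round(q) || q > s / 2)
    stop_invalid_spec(sprintf("n_harmonics must be an integer in [0, %d]", s / 2))
  C <- as.integer(C); q <- as.integer(q); s <- as.integer(s)

  nyquist <- (q == s %/% 2L)
  b <- if (nyquist) 2L + 2L * q - 1L else 2L + 2L * q  # block size per series
  p <- C * b

  # per-series transition block: trend then one rotation per harmonic
  Gb <- matrix(0, b, b)
  Gb[1:2, 1:2] <- matrix(c(1, 0, 1, 1), 2, 2)  # [[1,1],[0,1]]
  f_row <- numeric(b)
  f_row[1L] <- 1
  j_full <- if (nyquist) q - 1L else q
  for (j in seq_len(j_full)) {
    w <- 2 * pi * j / s
    idx <- 2L + 2L * (j - 1L) + 1:2
    Gb[idx, idx] <- matrix(c(cos(w), -sin(w), sin(w), cos(w)), 2, 2)
    f_row[idx[1L]] <- 1
  }
  if (nyquist && q >= 1L) {
    Gb[b, b] <- -1
    f_row[b] <- 1
  }

  G <- kronecker(diag(C), Gb)
  F_ <- kronecker(diag(C), matrix(f_row, nrow = 1))
  R <- matrix(0, p, C)
  for (cc in seq_len(C)) R[(cc - 1L) * b + 2L, cc] <- 1

  roles <- c("level", "slope")
  for (j in seq_len(j_full)) roles <- c(roles, paste0("harmonic_", j), paste0("conjugate_", j))
  if (nyquist && q >= 1L) roles <- c(roles, paste0("harmonic_", q))
  labels <- data.frame(series = rep(seq_len(C), each = b),
                       role = rep(roles, times = C),
                       stringsAsFactors = FALSE)

  structure(list(n_series = C, n_harmonics = q, period = s,
                 state_dim = p, block_size = b,
                 obs_matrix = F_, transition = G, evo_selection = R,
                 coord_labels = labels),
            class = "sutse_model")
}

stop_invalid_spec <- function(msg) {
  stop(structure(class = c("sutse_invalid_spec", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @export
print.sutse_model <- function(x, ...) {
  cat(sprintf("SUTSE DLM: %d series, %d harmonic(s), period %d, state dim %d\n",
              x$n_series, x$n_harmonics, x$period, x$state_dim))
  invisible(x)
}

#' Seasonal contribution of a series' harmonic states at a given month
#'
#' Propagates the seasonal blocks of the transition matrix `t` steps from the
#' state origin and returns the summed harmonic contribution
#' \eqn{\sum_j \xi_j(t)} for one series.  Exactly periodic with period `s`.
#'
#' @param spec a [build_model()] specification.
#' @param seasonal_state seasonal coordinates at the origin, length
#'   \eqn{2q} (or \eqn{2q-1} when \eqn{q = s/2}).
#' @param series series index (the seasonal dynamics are shared across
#'   series; the index is validated for interface symmetry).
#' @param t month index (integer, may be 0 or negative).
#' @return scalar seasonal value at month `t`.
#' @export
seasonal_value <- function(spec, seasonal_state, series = 1L, t) {
  stopifnot(inherits(spec, "sutse_model"))
  if (series < 1 || series > spec$n_series) stop("series index out of range")
  q <- spec$n_harmonics; s <- spec$period
  n_seas <- spec$block_size - 2L
  if (length(seasonal_state) != n_seas)
    stop(sprintf("seasonal state must have length %d, got %d",
                 n_seas, length(seasonal_state)))
  if (q == 0L) return(0)
  nyquist <- (q == s %/% 2L)
  j_full <- if (nyquist) q - 1L else q
  val <- 0
  for (j in seq_len(j_full)) {
    w <- 2 * pi * j * t / s
    sj <- seasonal_state[2L * (j - 1L) + 1:2]
    val <- val + cos(w) * sj[1L] + sin(w) * sj[2L]
  }
  if (nyquist) val <- val + (-1)^t * seasonal_state[n_seas]
  val
}

#' Observation-equation mean
#'
#' Returns \eqn{F\theta}: for each series the level plus the sum of its
#' harmonic (not conjugate) coordinates.
#'
#' @param spec a [build_model()] specification.
#' @param state state vector of length `spec$state_dim`.
#' @return numeric vector of length `n_series`.
#' @export
observation_mean <- function(spec, state) {
  stopifnot(inherits(spec, "sutse_model"))
  if (length(state) != spec$state_dim)
    stop(sprintf("state must have length %d, got %d",
                 spec$state_dim, length(state)))
  drop(spec$obs_matrix %*% state)
}

#' Serialize a model specification to JSON
#'
#' Dimensions and seasonal configuration only (the structural matrices are
#' reconstructable from these); intended for provenance metadata in output
#' files.
#'
#' @param spec a [build_model()] specification.
#' @param series_names optional character vector of series labels.
#' @return a JSON string.
#' @export
model_to_json <- function(spec, series_names = NULL) {
  stopifnot(inherits(spec, "sutse_model"))
  jsonlite::toJSON(list(n_series = spec$n_series,
                        n_harmonics = spec$n_harmonics,
                        period = spec$period,
                        state_dim = spec$state_dim,
                        series_names = series_names),
                   auto_unbox = TRUE, null = "null")
}
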