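#' Triangular random draws
#'
#' Inverse-transform sampling from a triangular distribution on
#' `[low, high]` with the given mode. Degenerate ranges return the point
#' mass.
#'
#' @param n Number of draws.
#' @param low,mode,high Distribution parameters, `low <= mode <= high`.
#' @return Numeric vector of length `n`.
#' @export
rtriangle <- function(n, low, mode, high) {
  stopifnot(low <= mode, mode <= high)
  if (high == low) return(rep(mode, n))
  u <- stats::runif(n)
  f <- (mode - low) / (high - low)
  ifelse(u < f,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

# Mean and variance of the triangular distribution (used by tests).
triangle_moments <- function(low, mode, high) {
  list(mean = (low + mode + high) / 3,
       var = (low^2 + mode^2 + high^2 -
                low * mode - low * high - mode * high) / 18)
}

# Method-of-moments beta parameters from a mean and SD; NULL when the
# moments are incompatible with a beta on (0, 1) (parameter then held fixed).
beta_from_moments <- function(mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1 || sd^2 >= mean * (1 - mean))
    return(NULL)
  alpha <- mean * (mean * (1 - mean) / sd^2 - 1)
  list(alpha = alpha, beta = alpha * (1 - mean) / mean)
}

#' Draw a joint parameter sample for the probabilistic sensitivity analysis
#'
#' Distribution families follow the analysis plan: triangular for cost
#' parameters (low/mode/high from the declared range with the base value as
#' mode), beta for utilities and proportions (method of moments with the
#' base value as mean and `(high - low)/4` as SD), and lognormal for hazard
#' ratios (centred on the log point estimate with the CI-derived SE of the
#' log hazard ratio). Parameters whose distribution cannot be resolved
#' (zero-width range, incompatible beta moments) are held at base with a
#' message.
#'
#' @param inputs A `model_inputs` object.
#' @param n Number of joint draws.
#' @return A data frame of `n` rows, one column per sampled parameter.
#' @export
draw_psa_parameters <- function(inputs, n) {
  table <- sens_parameter_table(inputs)
  draws <- lapply(names(table), function(nm) {
    p <- table[[nm]]
    if (p$dist == "triangle") {
      if (p$high == p$low) {
        message("PSA: `", nm, "` has a zero-width range; held fixed")
        return(rep(p$base, n))
      }
      return(rtriangle(n, p$low, p$base, p$high))
    }
    if (p$dist == "beta") {
      ab <- beta_from_moments(p$base, (p$high - p$low) / 4)
      if (is.null(ab)) {
        message("PSA: no resolvable beta for `", nm, "`; held fixed")
        return(rep(p$base, n))
      }
      return(stats::rbeta(n, ab$alpha, ab$beta))
    }
    if (p$dist == "lognormal") {
      if (p$log_se <= 0) {
        message("PSA: `", nm, "` has zero log-HR SE; held fixed")
        return(rep(p$base, n))
      }
      return(exp(stats::rnorm(n, log(p$base), p$log_se)))
    }
    stop("unknown PSA distribution for `", nm, "`", call. = FALSE)
  })
  names(draws) <- names(table)
  as.data.frame(draws)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter samples (see [draw_psa_parameters()]) and runs
#' the full cohort model for each strategy under every draw. Reproducible
#' under a fixed seed.
#'
#' @param inputs A `model_inputs` object.
#' @param n Number of draws (default 1000).
#' @param seed Integer seed.
#' @param strategies_run Strategies to evaluate (default all three).
#' @return A `psa_result`: list with `draws` (data frame: `draw`, `strategy`,
#'   `cost`, `qalys`), `parameters` (the sampled values), `n`, `seed`.
#' @export
run_psa <- function(inputs, n = 1000, seed = 1L,
                    strategies_run = strategies()) {
  stopifnot(n >= 1, all(strategies_run %in% strategies()))
  set.seed(seed)
  params <- draw_psa_parameters(inputs, n)
  table <- sens_parameter_table(inputs)
  per_draw <- function(i) {
    modified <- inputs
    for (nm in names(params))
      modified <- table[[nm]]$set(modified, params[[nm]][i])
    res <- lapply(strategies_run, function(s) {
      # PSA draws can make the PFS curve cross OS; the clamp in
      # build_trace() handles it, silently here.
      out <- suppressWarnings(run_strategy(modified, s))
      data.frame(draw = i, strategy = s, cost = out$costs$total,
                 qalys = out$qalys)
    })
    do.call(rbind, res)
  }
  draws <- do.call(rbind, lapply(seq_len(n), per_draw))
  structure(list(draws = draws, parameters = params, n = n, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), strategies: %s\n", x$n, x$seed,
              paste(unique(x$draws$strategy), collapse = ", ")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that a strategy is
#' cost-effective is the fraction of PSA draws in which its net monetary
#' benefit exceeds the comparator's.
#'
#' @param psa A [run_psa()] result containing the comparator and at least one
#'   other strategy.
#' @param wtp_grid Strictly increasing willingness-to-pay grid (USD/QALY);
#'   default 0 to 60,000 in steps of 1,000.
#' @param comparator Reference strategy tag (default `"control"`).
#' @return A data frame with columns `wtp`, `strategy`, `p_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 60000, by = 1000),
                 comparator = "control") {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L) stop("ceac: empty WTP grid", call. = FALSE)
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("ceac: WTP grid must be strictly increasing", call. = FALSE)
  d <- psa$draws
  if (!comparator %in% d$strategy)
    stop("ceac: comparator not present in the PSA", call. = FALSE)
  ref <- d[d$strategy == comparator, ]
  ref <- ref[order(ref$draw), ]
  others <- setdiff(unique(d$strategy), comparator)
  out <- lapply(others, function(s) {
    alt <- d[d$strategy == s, ]
    alt <- alt[order(alt$draw), ]
    dq <- alt$qalys - ref$qalys
    dc <- alt$cost - ref$cost
    p <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1L))
    data.frame(wtp = wtp_grid, strategy = s, p_ce = p)
  })
  do.call(rbind, out)
}
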