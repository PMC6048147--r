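# Bootstrap significance procedures: condition redraw, the conservative
# dimension redraw, and the generic neuron bootstrap, with a uniform
# p-value convention (p is never exactly 0; a zero count is reported as the
# bound 1/n_draws).

#' Bootstrap p-value convention
#'
#' The p-value is the fraction of draws in which the effect was not
#' observed; e.g. an effect present in the original data and in 995 of 1000
#' draws gives p = 0.005. A zero count is reported as the bound
#' `1/n_draws` with `bound = TRUE`.
#'
#' @param n_effect number of draws in which the effect was observed.
#' @param n_draws total number of draws.
#' @return list with `p_value` (in `(0, 1]`) and `bound` (`TRUE` if the
#'   p-value is the `< 1/n_draws` bound).
#' @export
bootstrap_pvalue <- function(n_effect, n_draws) {
  if (n_draws < 1 || n_effect < 0 || n_effect > n_draws)
    stopf("need 0 <= n_effect <= n_draws")
  n_not <- n_draws - n_effect
  if (n_not == 0) list(p_value = 1 / n_draws, bound = TRUE)
  else list(p_value = n_not / n_draws, bound = FALSE)
}

default_dyn_stat <- function(X, X_dot) fit_linear_dynamics(X, X_dot)$r2

new_bootstrap_result <- function(method, statistic, observed, draws, p,
                                 n_draws, seed, n_redrawn, extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   observed = observed, draws = draws,
                   p_value = p$p_value, p_is_bound = p$bound,
                   n_draws = n_draws, seed = seed, n_redrawn = n_redrawn),
              extra),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result (%s): %d draws (seed %d, %d redrawn)\n",
              x$method, x$n_draws, x$seed, x$n_redrawn))
  cat(sprintf("  p %s %.4g\n", if (x$p_is_bound) "<" else "=", x$p_value))
  invisible(x)
}

#' Condition-redraw bootstrap for comparing a statistic between two areas
#'
#' Each draw redraws, with replacement, `C` conditions from the original
#' `C`; both areas use the same redrawn condition multiset, and the
#' statistic (by default the unconstrained linear-dynamics `R^2`) is
#' recomputed for each. The p-value is the fraction of draws in which the
#' effect was not observed.
#'
#' @param X_a,X_dot_a latents and per-step derivatives for area a
#'   (`CT x k`, condition-major).
#' @param X_b,X_dot_b same for area b (same condition set).
#' @param condition condition label per row (shared by both areas).
#' @param stat `function(X, X_dot) -> scalar`; default unconstrained-fit
#'   `R^2`.
#' @param effect `function(stat_a, stat_b) -> logical`; default
#'   `stat_a > stat_b`.
#' @param n_draws number of bootstrap draws (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return a `bootstrap_result` with `observed` (statistics and effect on
#'   the original data), per-draw statistics in `draws`, and `p_value`.
#' @export
bootstrap_conditions <- function(X_a, X_dot_a, X_b, X_dot_b, condition,
                                 stat = default_dyn_stat,
                                 effect = function(a, b) a > b,
                                 n_draws = 1000, seed = 1) {
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  X_dot_a <- as.matrix(X_dot_a); X_dot_b <- as.matrix(X_dot_b)
  if (n_draws < 100) warning("n_draws < 100 gives a coarse p-value")
  condition <- as.character(condition)
  groups <- split(seq_along(condition), factor(condition, unique(condition)))
  C <- length(groups)
  if (C < 2) stopf("need at least 2 conditions")
  s_a0 <- stat(X_a, X_dot_a); s_b0 <- stat(X_b, X_dot_b)
  draws <- data.frame(stat_a = numeric(n_draws), stat_b = numeric(n_draws),
                      effect = logical(n_draws))
  n_redrawn <- 0L
  with_seed(derive_seed(seed, 41), {
    for (b in seq_len(n_draws)) {
      repeat {
        rows <- unlist(groups[sample(C, C, replace = TRUE)], use.names = FALSE)
        ok <- tryCatch({
          sa <- stat(X_a[rows, , drop = FALSE], X_dot_a[rows, , drop = FALSE])
          sb <- stat(X_b[rows, , drop = FALSE], X_dot_b[rows, , drop = FALSE])
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_draws) stopf("too many failed bootstrap draws")
      }
      draws$stat_a[b] <- sa; draws$stat_b[b] <- sb
      draws$effect[b] <- isTRUE(effect(sa, sb))
    }
  })
  p <- bootstrap_pvalue(sum(draws$effect), n_draws)
  new_bootstrap_result("condition", "stat comparison",
                       list(stat_a = s_a0, stat_b = s_b0,
                            effect = isTRUE(effect(s_a0, s_b0))),
                       draws, p, n_draws, seed, n_redrawn)
}

#' Conservative dimension-redraw bootstrap
#'
#' Treats the four dynamical dimensions of each area as eight dimensions of
#' one undifferentiated pool. Each draw picks four random dimensions from
#' the pool (twice, independently, overlap allowed unless
#' `disjoint = TRUE`), computes the statistic difference between the two
#' pseudo-areas, and builds the null distribution of such differences. The
#' default p-value is the fraction of draws whose |difference| is at least
#' the observed |difference|.
#'
#' @param X_a,X_b latents of the two areas (`CT x 4` each, same rows).
#' @param X_dot_a,X_dot_b matching per-step derivatives.
#' @param stat `function(X, X_dot) -> scalar`; default unconstrained-fit
#'   `R^2`.
#' @param n_draws number of draws (default 1000).
#' @param seed RNG seed.
#' @param disjoint if `TRUE`, the second pseudo-area uses the complementary
#'   four dimensions.
#' @param sided `"two"` (default; counts `|diff| >= |observed|`) or
#'   `"greater"` (counts signed `diff >= observed`).
#' @return a `bootstrap_result`; `draws$diff` holds the null differences.
#' @export
bootstrap_dimensions <- function(X_a, X_b, X_dot_a, X_dot_b,
                                 stat = default_dyn_stat,
                                 n_draws = 1000, seed = 1,
                                 disjoint = FALSE,
                                 sided = c("two", "greater")) {
  sided <- match.arg(sided)
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  ka <- ncol(X_a)
  if (ncol(X_b) != ka) stopf("both areas must have the same dimension count")
  P <- cbind(X_a, X_b)
  Pd <- cbind(as.matrix(X_dot_a), as.matrix(X_dot_b))
  observed <- stat(X_a, as.matrix(X_dot_a)) - stat(X_b, as.matrix(X_dot_b))
  diffs <- numeric(n_draws)
  n_redrawn <- 0L
  with_seed(derive_seed(seed, 42), {
    for (b in seq_len(n_draws)) {
      repeat {
        s1 <- sample(2 * ka, ka)
        s2 <- if (disjoint) setdiff(seq_len(2 * ka), s1) else sample(2 * ka, ka)
        ok <- tryCatch({
          d <- stat(P[, s1, drop = FALSE], Pd[, s1, drop = FALSE]) -
            stat(P[, s2, drop = FALSE], Pd[, s2, drop = FALSE])
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_draws) stopf("too many failed bootstrap draws")
      }
      diffs[b] <- d
    }
  })
  n_as_large <- if (sided == "two") sum(abs(diffs) >= abs(observed))
  else sum(diffs >= observed)
  # "effect observed" in a draw = null difference smaller than the observed
  p <- bootstrap_pvalue(n_draws - n_as_large, n_draws)
  new_bootstrap_result("dimension", "stat difference",
                       list(diff = observed), data.frame(diff = diffs),
                       p, n_draws, seed, n_redrawn,
                       extra = list(sided = sided, disjoint = disjoint))
}

#' Neuron bootstrap with confidence intervals
#'
#' Redraws the unit population with replacement and reruns an arbitrary
#' analysis, reporting the mean and SEM (standard deviation across draws)
#' of each scalar output.
#'
#' @param resp a [population_response()].
#' @param analysis `function(resp) -> named numeric vector`.
#' @param n_draws number of redraws (default 100).
#' @param seed RNG seed.
#' @return a `bootstrap_result` with `draws` (draws x outputs matrix),
#'   `mean` and `sem` named vectors.
#' @export
bootstrap_neurons <- function(resp, analysis, n_draws = 100, seed = 1) {
  stopifnot(inherits(resp, "population_response"))
  N <- dim(resp$rates)[3]
  if (N < 2) stopf("need at least 2 units")
  observed <- analysis(resp)
  draws <- matrix(NA_real_, n_draws, length(observed),
                  dimnames = list(NULL, names(observed)))
  n_redrawn <- 0L
  with_seed(derive_seed(seed, 43), {
    for (b in seq_len(n_draws)) {
      repeat {
        idx <- sample(N, N, replace = TRUE)
        sub <- resp
        sub$rates <- resp$rates[, , idx, drop = FALSE]
        sub$units <- data.frame(
          unit_id = sprintf("b%04d", seq_len(N)),
          population_label = resp$units$population_label[idx])
        out <- tryCatch(analysis(sub), error = function(e) NULL)
        if (!is.null(out)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_draws) stopf("too many failed bootstrap draws")
      }
      draws[b, ] <- out
    }
  })
  new_bootstrap_result("neuron", "analysis outputs",
                       observed, draws,
                       list(p_value = 1, bound = FALSE),
                       n_draws, seed, n_redrawn,
                       extra = list(mean = colMeans(draws),
                                    sem = apply(draws, 2, stats::sd)))
}

#' Serialize a bootstrap result to JSON (including full draw vectors)
#' @param x a `bootstrap_result`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_bootstrap_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
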