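# Monte Carlo propagation of relative-risk uncertainty. Each association's
# RR is redrawn from a log-normal with median at the point estimate and
# log-SD set from its 95% CI; the scenario is re-run per draw and the 5th,
# 25th, 50th, 75th and 95th percentiles of deaths averted summarise the
# credible distribution.

#' Redraw association relative risks from their confidence intervals
#'
#' Each `rr` is replaced by a draw from a log-normal with median `rr` and
#' `sdlog = (log(ci_high) - log(ci_low)) / (2 * 1.96)`; draws are
#' independent across associations and deterministic given `seed`. A
#' degenerate CI (`ci_low == ci_high == rr`) reproduces `rr` exactly.
#'
#' @param assocs List of [risk_association()]s.
#' @param seed Integer seed for this draw.
#' @return List of associations with resampled `rr` (CI fields untouched).
#' @export
sample_associations <- function(assocs, seed) {
  for (a in assocs) {
    if (a$ci_high < a$ci_low) {
      stop(sprintf("association %s -> %s: ci_high < ci_low", a$factor, a$disease),
           call. = FALSE)
    }
  }
  with_stream(seed, 0L, {
    lapply(assocs, function(a) {
      sdlog <- (log(a$ci_high) - log(a$ci_low)) / (2 * stats::qnorm(0.975))
      a$rr <- if (sdlog == 0) a$rr else stats::rlnorm(1, log(a$rr), sdlog)
      a
    })
  })
}

PCTL_PROBS <- c(p5 = 0.05, p25 = 0.25, p50 = 0.50, p75 = 0.75, p95 = 0.95)

summary_keys <- function(agg) {
  c(list(total = agg$total, cardiovascular = agg$cardiovascular,
         cancer = agg$cancer, other = agg$other),
    as.list(agg$per_cause))
}

# Derive one sub-seed per draw from the top-level seed (counter scheme:
# results do not depend on execution order across draws or labels).
draw_seeds <- function(seed, n_draws) {
  (as.integer(seed) + 99991L * seq_len(n_draws)) %% .Machine$integer.max
}

#' Monte Carlo credible summary for one scenario
#'
#' Runs the scenario once with the point-estimate RRs, then `n_draws` times
#' with RRs resampled by [sample_associations()], and summarises deaths
#' averted per key (total, cardiovascular, cancer, other, and each cause)
#' by the 5th/25th/50th/75th/95th percentiles across draws (linear
#' interpolation between order statistics).
#'
#' @param pop,mort,base,cf,assocs Scenario inputs as in [run_scenario()].
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Top-level seed; per-draw sub-seeds are derived by counter, so
#'   the summary is reproducible from `(seed, n_draws, inputs)`.
#' @param method Shift method passed to [run_scenario()].
#' @param seeds Optional explicit vector of per-draw seeds (length
#'   `n_draws`); used by [run_all()] to share one draw set across labels.
#' @return A `credible_summary`: list with `point` (named point estimates),
#'   `percentiles` (matrix keys x p5..p95), `n_draws`, `seed`.
#' @export
monte_carlo_scenario <- function(pop, mort, base, cf, assocs,
                                 n_draws = 2000, seed = 1L,
                                 method = "mean_shift", seeds = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (is.null(seeds)) seeds <- draw_seeds(seed, n_draws)
  if (length(seeds) != n_draws) stop("length(seeds) must equal n_draws", call. = FALSE)
  point <- summary_keys(aggregate_averted(
    run_scenario(pop, mort, base, cf, assocs, method = method)))
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(point),
                  dimnames = list(NULL, names(point)))
  for (i in seq_len(n_draws)) {
    res <- tryCatch(
      run_scenario(pop, mort, base, cf,
                   sample_associations(assocs, seeds[i]), method = method),
      error = function(e) {
        stop(sprintf("Monte Carlo draw %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    draws[i, ] <- unlist(summary_keys(aggregate_averted(res)))
  }
  pct <- t(apply(draws, 2, stats::quantile, probs = PCTL_PROBS,
                 names = FALSE, type = 7))
  colnames(pct) <- names(PCTL_PROBS)
  structure(list(point = unlist(point), percentiles = pct,
                 n_draws = n_draws, seed = as.integer(seed)),
            class = "credible_summary")
}

#' @export
print.credible_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Credible summary (%d draws, seed %d)\n", x$n_draws, x$seed))
  keys <- c("total", "cardiovascular", "cancer", "other")
  for (k in keys) {
    cat(sprintf("  %-15s %10.*f  (p5 %.*f, p95 %.*f)\n", k, digits,
                x$point[[k]], digits, x$percentiles[k, "p5"],
                digits, x$percentiles[k, "p95"]))
  }
  invisible(x)
}

#' Run every label x variant scenario end-to-end
#'
#' For each requested (label, variant) pair, builds the counterfactual diet
#' from the matching effect table, runs the Monte Carlo credible summary,
#' and ranks labels by total deaths averted (point estimate). RR draws are
#' shared across labels within a run by default (the same draw of each
#' association is applied to every label), so between-label differences are
#' not blurred by sampling noise; set `common_draws = FALSE` for
#' independent draws per label.
#'
#' @param pop,mort,base,assocs Inputs as in [run_scenario()].
#' @param effects Named list of effect tables from [read_effect_table()].
#' @param labels,variants Character vectors selecting scenarios; every
#'   (label, variant) pair must exist in `effects`.
#' @param n_draws,seed,method As in [monte_carlo_scenario()].
#' @param common_draws Share RR draws across labels (default TRUE).
#' @param spec_args Extra arguments passed to [scenario_spec()] (e.g.
#'   `sd_scaling`, `portion_handling`).
#' @return A `fopl_report`: list with `summaries` (named
#'   `credible_summary` list), `ranking` (data frame of label/variant by
#'   decreasing total averted), `n_draws`, `seed`, `method`,
#'   `common_draws`.
#' @export
run_all <- function(pop, mort, base, assocs, effects = read_effect_table(),
                    labels = LABEL_IDS, variants = "mean",
                    n_draws = 2000, seed = 1L, method = "mean_shift",
                    common_draws = TRUE, spec_args = list()) {
  wanted <- expand.grid(label = labels, variant = variants,
                        stringsAsFactors = FALSE)
  keys <- paste(wanted$label, wanted$variant, sep = "/")
  missing_keys <- setdiff(keys, names(effects))
  if (length(missing_keys)) {
    stop(sprintf("missing effect table(s): %s", paste(missing_keys, collapse = ", ")),
         call. = FALSE)
  }
  shared <- draw_seeds(seed, n_draws)
  summaries <- list()
  for (i in seq_len(nrow(wanted))) {
    lab <- wanted$label[i]; var <- wanted$variant[i]
    spec <- do.call(scenario_spec, c(list(label = lab, variant = var), spec_args))
    cf <- build_counterfactual(base, effects[[keys[i]]], spec)
    seeds_i <- if (common_draws) shared else draw_seeds(seed + i * 1000003L, n_draws)
    summaries[[keys[i]]] <- monte_carlo_scenario(
      pop, mort, base, cf, assocs, n_draws = n_draws, seed = seed,
      method = method, seeds = seeds_i)
  }
  ranking <- data.frame(label = wanted$label, variant = wanted$variant,
                        total_averted = vapply(keys, function(k) {
                          summaries[[k]]$point[["total"]]
                        }, numeric(1)),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$total_averted), ]
  rownames(ranking) <- NULL
  structure(list(summaries = summaries, ranking = ranking,
                 n_draws = n_draws, seed = as.integer(seed), method = method,
                 common_draws = common_draws, schema_version = "1.0"),
            class = "fopl_report")
}

#' @export
print.fopl_report <- function(x, ...) {
  cat(sprintf("FoPL mortality report: %d scenario(s), %d draws, seed %d\n",
              length(x$summaries), x$n_draws, x$seed))
  cat("Ranking by total deaths averted (point estimate):\n")
  for (i in seq_len(nrow(x$ranking))) {
    k <- paste(x$ranking$label[i], x$ranking$variant[i], sep = "/")
    s <- x$summaries[[k]]
    cat(sprintf("  %2d. %-22s %10.1f  (p5 %.1f, p95 %.1f)\n", i, k,
                s$point[["total"]], s$percentiles["total", "p5"],
                s$percentiles["total", "p95"]))
  }
  invisible(x)
}

#' @export
summary.fopl_report <- function(object, ...) {
  rows <- lapply(names(object$summaries), function(k) {
    s <- object$summaries[[k]]
    lv <- strsplit(k, "/", fixed = TRUE)[[1]]
    data.frame(label = lv[1], variant = lv[2],
               total = s$point[["total"]],
               cardiovascular = s$point[["cardiovascular"]],
               cancer = s$point[["cancer"]],
               other = s$point[["other"]],
               p5 = s$percentiles["total", "p5"],
               p50 = s$percentiles["total", "p50"],
               p95 = s$percentiles["total", "p95"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$total), ]
}

#' Plot deaths averted by label with credible intervals
#'
#' Base-graphics bar chart of total deaths averted (point estimate) per
#' scenario, with p5-p95 whiskers.
#'
#' @param x A `fopl_report`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.fopl_report <- function(x, ...) {
  s <- summary(x)
  heights <- s$total
  names(heights) <- paste(s$label, s$variant, sep = "\n")
  mids <- graphics::barplot(heights, ylab = "Deaths averted or delayed",
                            ylim = range(0, s$p5, s$p95) * 1.05, ...)
  graphics::arrows(mids, s$p5, mids, s$p95, angle = 90, code = 3, length = 0.05)
  invisible(x)
}

#' Serialise a report to versioned JSON
#'
#' @param report A `fopl_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "fopl_report"))
  body <- list(
    schema_version = report$schema_version,
    seed = report$seed, n_draws = report$n_draws, method = report$method,
    common_draws = report$common_draws,
    ranking = report$ranking,
    scenarios = lapply(report$summaries, function(s) {
      list(point = as.list(s$point),
           percentiles = apply(s$percentiles, 1, as.list, simplify = FALSE))
    }))
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
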