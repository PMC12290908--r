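# --- parameter-path resolution ------------------------------------------------
# A spec name is a dot path into the bundle, e.g. "costs.rrm" or
# "utilities.decrements.prevention". A path may end inside a data frame with
# two final segments <column>.<row key>, the row key matched against the
# frame's first column (e.g. "costs.treatment.first_year.stage2").

bundle_get <- function(bundle, name) {
  segs <- strsplit(name, ".", fixed = TRUE)[[1]]
  cur <- bundle
  i <- 1
  while (i <= length(segs)) {
    if (is.data.frame(cur)) {
      if (length(segs) - i != 1) {
        abort_rrmcea(sprintf("path '%s': expected <column>.<row> inside a table",
                             name), "rrmcea_config_error")
      }
      col <- segs[i]; key <- segs[i + 1]
      row <- match(key, cur[[1]])
      if (!col %in% names(cur) || is.na(row)) {
        abort_rrmcea(sprintf("path '%s' not found", name),
                     "rrmcea_config_error")
      }
      return(cur[[col]][row])
    }
    if (!is.list(cur) || is.null(cur[[segs[i]]])) {
      abort_rrmcea(sprintf("path '%s' not found", name), "rrmcea_config_error")
    }
    cur <- cur[[segs[i]]]
    i <- i + 1
  }
  if (!is.numeric(cur) || length(cur) != 1) {
    abort_rrmcea(sprintf("path '%s' does not resolve to one scalar", name),
                 "rrmcea_config_error")
  }
  cur
}

bundle_set <- function(bundle, name, value) {
  bundle_get(bundle, name)  # existence + scalar check
  value <- unname(value)
  segs <- strsplit(name, ".", fixed = TRUE)[[1]]
  assign_in <- function(cur, segs) {
    if (is.data.frame(cur)) {
      row <- match(segs[2], cur[[1]])
      cur[[segs[1]]][row] <- value
      return(cur)
    }
    if (length(segs) == 1) {
      cur[[segs[1]]] <- value
      return(cur)
    }
    cur[[segs[1]]] <- assign_in(cur[[segs[1]]], segs[-1])
    cur
  }
  assign_in(bundle, segs)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each parameter spec, the ICER of RRM vs screening is recomputed with
#' that parameter at its low and at its high value, all others held at their
#' point values. Entries are returned sorted by ICER spread, the tornado
#' ordering.
#'
#' @param bundle Parameter bundle.
#' @param specs Parameter specs tibble (`name`, `point`, `low`, `high`,
#'   `distribution`, `se`), e.g. from [default_param_specs()]. Default ranges
#'   follow the convention: probabilities and utilities +/-10%, costs +/-30%.
#' @param lifetime_risk,start_age Scenario at which the tornado is computed.
#' @return Tibble of class `bc_tornado`, sorted by `spread` descending:
#'   `name`, `icer_at_low`, `icer_at_high`, `spread`, plus `icer_base`.
#' @export
owsa <- function(bundle, specs, lifetime_risk, start_age) {
  base <- evaluate_scenario(bundle, lifetime_risk, start_age)$icer$icer
  icer_at <- function(name, value) {
    b <- bundle_set(bundle, name, value)
    evaluate_scenario(b, lifetime_risk, start_age)$icer$icer
  }
  out <- purrr::pmap_dfr(specs[c("name", "low", "high")],
                         function(name, low, high) {
    lo <- icer_at(name, low)
    hi <- icer_at(name, high)
    tibble::tibble(name = name, icer_at_low = lo, icer_at_high = hi,
                   spread = abs(hi - lo))
  })
  out$icer_base <- base
  out <- dplyr::arrange(out, dplyr::desc(.data$spread))
  class(out) <- c("bc_tornado", class(out))
  out
}

#' Draw one parameter bundle for probabilistic sensitivity analysis
#'
#' Samples each spec from its assigned distribution, parameterized by moment
#' matching on (point, se):
#' * `GAMMA` (costs): shape `(m/se)^2`, scale `se^2/m`;
#' * `BETA` (probabilities): method of moments; if `se^2 >= m(1-m)` the se is
#'   shrunk to feasibility first;
#' * `LOGNORMAL` (utility scores): moments matched on the log scale, draws
#'   above 1 truncated to 1;
#' * `FIXED`: the point value.
#'
#' `se = 0` (or `NA` with `FIXED`) degenerates to the point value. Uses the
#' current RNG stream; seed once per PSA run.
#'
#' @param specs Parameter specs tibble (`name`, `point`, `low`, `high`,
#'   `distribution`, `se`).
#' @return Named numeric vector of drawn values, one per spec.
#' @export
draw_parameters <- function(specs) {
  draw1 <- function(name, point, low, high, distribution, se) {
    if (distribution != "FIXED" && (is.na(se) || se < 0)) {
      abort_rrmcea(sprintf("spec '%s': se must be >= 0", name),
                   "rrmcea_spec_error")
    }
    if (distribution == "FIXED" || isTRUE(se == 0) || point == 0) {
      return(point)
    }
    switch(distribution,
      GAMMA = stats::rgamma(1, shape = (point / se)^2,
                            scale = se^2 / point),
      BETA = {
        v <- min(se^2, 0.95 * point * (1 - point))
        nu <- point * (1 - point) / v - 1
        stats::rbeta(1, point * nu, (1 - point) * nu)
      },
      LOGNORMAL = {
        s2 <- log(1 + se^2 / point^2)
        x <- stats::rlnorm(1, log(point) - s2 / 2, sqrt(s2))
        if (point <= 1) min(x, 1) else x
      },
      abort_rrmcea(sprintf("spec '%s': unknown distribution '%s'",
                           name, distribution), "rrmcea_spec_error")
    )
  }
  out <- purrr::pmap_dbl(
    specs[c("name", "point", "low", "high", "distribution", "se")], draw1)
  stats::setNames(out, specs$name)
}

#' Probabilistic sensitivity analysis with acceptability curve
#'
#' Redraws all spec'd parameters jointly `n` times (one shared RNG stream,
#' seeded once), reruns both model arms per draw, and summarizes the
#' probability that RRM is cost-effective — the fraction of draws with
#' positive net monetary benefit — at each willingness-to-pay value on the
#' grid (the CEAC). Bit-reproducible for a fixed seed. A draw producing a
#' bundle that fails validation is redrawn (counted); a redraw rate above 1%
#' is an error.
#'
#' @param bundle Parameter bundle.
#' @param specs Parameter specs tibble; default [default_param_specs()].
#' @param n Number of simulations (the reference analysis uses 10 000).
#' @param seed Integer RNG seed.
#' @param lifetime_risk,start_age Scenario evaluated.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @return Object of class `bc_psa`: list with `n`, `seed`, `draws` (tibble:
#'   per-simulation costs/QALYs per arm and deltas), `ceac` (tibble: `wtp`,
#'   `probability`), `n_redraws`.
#' @export
psa <- function(bundle, specs = default_param_specs(bundle), n, seed,
                lifetime_risk, start_age,
                wtp_grid = seq(0, 50000, by = 2500)) {
  if (n < 1) abort_rrmcea("n must be >= 1", "rrmcea_domain_error")
  set.seed(seed)
  n_redraws <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      vals <- draw_parameters(specs)
      b <- bundle
      for (j in seq_along(vals)) b <- bundle_set(b, names(vals)[j], vals[j])
      rep_tbl <- validate_params(b)
      if (nrow(rep_tbl) == 0) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max(1, 0.01 * n)) {
        abort_rrmcea("PSA redraw rate exceeded 1%", "rrmcea_psa_error")
      }
    }
    res <- evaluate_scenario(b, lifetime_risk, start_age)
    rows[[i]] <- tibble::tibble(
      sim = i,
      cost_screen = res$screen$discounted_cost,
      qaly_screen = res$screen$discounted_qaly,
      cost_rrm = res$rrm$discounted_cost,
      qaly_rrm = res$rrm$discounted_qaly)
  }
  draws <- dplyr::mutate(dplyr::bind_rows(rows),
                         delta_cost = .data$cost_rrm - .data$cost_screen,
                         delta_qaly = .data$qaly_rrm - .data$qaly_screen)
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    probability = purrr::map_dbl(wtp_grid, function(w) {
      mean(net_monetary_benefit(draws$delta_cost, draws$delta_qaly, w) > 0)
    }))
  structure(list(n = as.integer(n), seed = as.integer(seed), draws = draws,
                 ceac = ceac, n_redraws = n_redraws,
                 lifetime_risk = lifetime_risk,
                 start_age = as.integer(start_age)),
            class = "bc_psa")
}

#' @export
print.bc_psa <- function(x, ...) {
  cat(sprintf(
    "<bc_psa> %d simulations (seed %d) | risk %.0f%%, age %d | P(CE at 30k) = %.3f\n",
    x$n, x$seed, 100 * x$lifetime_risk, x$start_age,
    mean(net_monetary_benefit(x$draws$delta_cost, x$draws$delta_qaly,
                              30000) > 0)))
  invisible(x)
}
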