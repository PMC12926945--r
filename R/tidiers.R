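# broom-style tidiers for fitted/compared objects.

#' Tidy a Wilcoxon signed-rank result
#'
#' @param x A `parch_wilcoxon` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `w_plus`, `w_minus`, `n_effective`,
#'   `p_value`, `method`, `verdict`, `degenerate`.
#' @export
tidy.parch_wilcoxon <- function(x, ...) {
  tibble(
    statistic = x$statistic, w_plus = x$w_plus, w_minus = x$w_minus,
    n_effective = x$n_effective, p_value = x$p_value, method = x$method,
    verdict = x$verdict, degenerate = x$degenerate
  )
}

#' Tidy a PTM delta report
#'
#' `tidy()` returns one row per residue (the site plus every neighborhood
#' residue) with both PARCH values, the delta and its class; `glance()`
#' returns the one-row site-level summary including the cumulative
#' neighborhood change and the Wilcoxon verdict.
#'
#' @param x A `parch_delta` from [compute_delta()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.parch_delta <- function(x, ...) {
  bind_rows(
    mutate(x$site, role = "site"),
    mutate(x$neighbors, role = "neighbor")
  )
}

#' @rdname tidy.parch_delta
#' @export
glance.parch_delta <- function(x, ...) {
  tibble(
    chain = x$site$chain, resno = x$site$resno,
    resname_unmod = x$site$resname_unmod,
    resname_mod = x$site$resname_mod,
    pv_unmod = x$site$pv_unmod, pv_mod = x$site$pv_mod,
    site_delta = x$site_delta, site_class = x$site_class,
    n_neighbors = nrow(x$neighbors),
    cumulative_delta = x$cumulative_delta,
    wilcoxon_p = x$wilcoxon$p_value,
    verdict = x$wilcoxon$verdict
  )
}

#' Tidy a PARCH profile
#'
#' A `parch_profile` is already tibble-shaped; `tidy()` strips the class
#' and adds a `residue` label, `glance()` summarises the profile.
#'
#' @param x A `parch_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.parch_profile <- function(x, ...) {
  as_tibble(x) |>
    mutate(residue = paste0(.data$resname, .data$resno))
}

#' @rdname tidy.parch_profile
#' @export
glance.parch_profile <- function(x, ...) {
  tibble(
    n_residues = nrow(x),
    n_rep = max(x$n_rep),
    pv_min = min(x$pv_mean), pv_max = max(x$pv_mean),
    pv_median = stats::median(x$pv_mean),
    n_buried = sum(x$buried)
  )
}
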