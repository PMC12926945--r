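# PTM hydropathy comparison: site ΔPV, 3 Å (0.3 nm) neighborhood deltas,
# ±0.2 significance classification, cumulative neighborhood change, and a
# paired exact Wilcoxon signed-rank test over neighborhood residues.

#' Comparison parameters
#'
#' @param neighbor_cutoff Heavy-atom minimum-distance cutoff (nm) defining
#'   the neighborhood around a modification site (default 0.3, i.e. 3 Å,
#'   boundary inclusive).
#' @param delta_threshold PARCH-unit threshold: |ΔPV| must exceed it for a
#'   residue to be classified as a meaningful `increase`/`decrease`
#'   (default 0.2, an empirical choice, kept configurable).
#' @param cumulative_mode `"filtered"` (default): cumulative neighborhood
#'   change sums signed deltas only over neighbors passing the threshold;
#'   `"all"`: sums over every neighbor.
#' @param alpha Significance level for the Wilcoxon verdict (default 0.05).
#' @return A `compare_params` list.
#' @export
compare_params <- function(neighbor_cutoff = 0.3, delta_threshold = 0.2,
                           cumulative_mode = c("filtered", "all"),
                           alpha = 0.05) {
  assert_scalar_number(neighbor_cutoff, "neighbor_cutoff", positive = TRUE)
  assert_scalar_number(delta_threshold, "delta_threshold", positive = TRUE)
  cumulative_mode <- match.arg(cumulative_mode)
  structure(
    list(neighbor_cutoff = neighbor_cutoff,
         delta_threshold = delta_threshold,
         cumulative_mode = cumulative_mode, alpha = alpha),
    class = "compare_params"
  )
}

#' Residues neighboring a modification site
#'
#' All protein residues (excluding the site itself) having at least one
#' heavy atom within `neighbor_cutoff` of any heavy atom of the site
#' residue, measured on the supplied structure. The unmodified equilibrated
#' structure is the conventional choice so both variants share one residue
#' set.
#'
#' @param structure A `parch_structure`.
#' @param chain,resno Site residue key.
#' @param params A [compare_params()] object.
#' @return Tibble with columns `chain`, `resno`, `resname`, `min_dist`.
#' @export
find_neighborhood <- function(structure, chain, resno,
                              params = compare_params()) {
  tbl <- as_tibble(structure)
  prot <- protein_rows(structure) & tbl$is_heavy
  site_rows <- which(prot & tbl$chain == chain & tbl$resno == resno)
  if (length(site_rows) == 0) {
    abort(sprintf("site residue %s:%s not found", chain, resno))
  }
  other_rows <- which(prot) |> setdiff(site_rows)
  if (length(other_rows) == 0) {
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), min_dist = numeric()))
  }
  d <- min_dist_to_set(xyz_matrix(tbl, other_rows),
                       xyz_matrix(tbl, site_rows))
  tibble(
    chain = tbl$chain[other_rows], resno = tbl$resno[other_rows],
    resname = tbl$resname[other_rows], dist = d
  ) |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(min_dist = min(.data$dist), .groups = "drop") |>
    filter(.data$min_dist <= params$neighbor_cutoff) |>
    arrange(.data$chain, .data$resno)
}

#' Paired Wilcoxon signed-rank test with exact enumeration
#'
#' Classical signed-rank test on paired values: zero differences are
#' dropped, absolute differences are mid-ranked, and `W = min(W+, W-)`.
#' For `n_effective <= exact_max_n` (default 25) the two-sided p-value is
#' exact, from the full distribution of the signed-rank sum over all 2^n
#' sign assignments (computed by convolution, honouring tied ranks); above
#' that a normal approximation with tie correction and continuity
#' correction is used. All-zero differences give the degenerate result
#' p = 1 with `degenerate = TRUE`.
#'
#' @param x Unmodified-state values, a two-column data frame of pairs, or a
#'   vector of differences when `y` is omitted and `x` isn't a data frame.
#' @param y Modified-state values (paired with `x`); differences are
#'   `y - x`.
#' @param exact_max_n Largest `n_effective` for exact enumeration.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A `parch_wilcoxon` list: `statistic` (W), `w_plus`, `w_minus`,
#'   `n_effective`, `p_value`, `method`, `verdict` (`"significant"` or
#'   `"ns"`), `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))  # exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25,
                                 alpha = 0.05) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    d <- x[[2]] - x[[1]]
  } else if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    d <- y - x
  } else {
    d <- x
  }
  if (length(d) < 1) abort("at least one pair is required")
  d <- d[!is.na(d)]
  d_nz <- d[d != 0]
  n <- length(d_nz)
  if (n == 0) {
    out <- list(statistic = 0, w_plus = 0, w_minus = 0, n_effective = 0L,
                p_value = 1, method = "degenerate",
                verdict = "ns", degenerate = TRUE)
    class(out) <- "parch_wilcoxon"
    return(out)
  }
  r <- rank(abs(d_nz))
  w_plus <- sum(r[d_nz > 0])
  w_minus <- sum(r[d_nz < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_max_n) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    method <- "normal_approx"
  }
  out <- list(
    statistic = w, w_plus = w_plus, w_minus = w_minus,
    n_effective = as.integer(n), p_value = p, method = method,
    verdict = if (p < alpha) "significant" else "ns", degenerate = FALSE
  )
  class(out) <- "parch_wilcoxon"
  out
}

# Exact two-sided p for the signed-rank statistic given the (possibly
# mid-ranked) ranks of |differences|. Works on doubled ranks so tied
# mid-ranks stay integral; the null distribution of W+ is obtained by
# convolving (1 + x^(2 r_i)) over ranks. Two-sided p sums both tails,
# using the symmetry of the null distribution about S/2.
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- round(2 * w_obs)
  lower <- sum(f[seq_len(w2 + 1)])              # P(W+ <= w)
  upper <- sum(f[seq.int(total - w2 + 1, total + 1)]) # P(W+ >= S - w)
  min(1, lower + upper)
}

#' @export
print.parch_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: W = %g, n = %d, p = %.5g (%s) -> %s\n",
    x$statistic, x$n_effective, x$p_value, x$method, x$verdict
  ))
  invisible(x)
}

classify_delta <- function(delta, threshold) {
  dplyr::case_when(
    delta > threshold ~ "increase",
    delta < -threshold ~ "decrease",
    .default = "unchanged"
  )
}

#' PTM-induced hydropathy change at a site and its neighborhood
#'
#' Joins the unmodified and modified PARCH profiles through the residue
#' mapping, computes `delta = PV_mod - PV_unmod` for the site and each
#' neighborhood residue, classifies every delta against the ±threshold,
#' sums the cumulative neighborhood change, and runs the paired Wilcoxon
#' signed-rank test over the neighborhood PV pairs (per-residue replicate
#' means).
#'
#' @param parch_unmod,parch_mod `parch_profile` tibbles for the two
#'   variants.
#' @param mapping Residue mapping from [map_residues()].
#' @param site One-row data frame (or list) with `chain`, `resno` keying
#'   the site in the *unmodified* numbering, e.g. a row of
#'   [identify_ptm_sites()] output on the modified structure mapped back,
#'   or of the unmodified structure.
#' @param neighborhood Neighborhood tibble from [find_neighborhood()]
#'   (unmodified-structure keys); when `NULL` and `structure` is given it
#'   is computed.
#' @param structure Optional unmodified `parch_structure` used to compute
#'   the neighborhood.
#' @param params A [compare_params()] object.
#' @return A `parch_delta` object: `site` (tibble row with PVs and delta),
#'   `site_delta`, `site_class`, `neighbors` (tibble with `pv_unmod`,
#'   `pv_mod`, `delta`, `class`), `cumulative_delta`, `wilcoxon`
#'   (a `parch_wilcoxon`), `params`.
#' @export
compute_delta <- function(parch_unmod, parch_mod, mapping, site,
                          neighborhood = NULL, structure = NULL,
                          params = compare_params()) {
  site <- as_tibble(as.list(site)[c("chain", "resno")])
  site$resno <- as.integer(site$resno)
  if (is.null(neighborhood)) {
    if (is.null(structure)) {
      abort("supply either `neighborhood` or `structure`")
    }
    neighborhood <- find_neighborhood(structure, site$chain, site$resno,
                                      params)
  }
  paired <- mapping |>
    inner_join(as_tibble(parch_unmod) |>
                 select(chain_unmod = "chain", resno_unmod = "resno",
                        pv_unmod = "pv_mean"),
               by = c("chain_unmod", "resno_unmod")) |>
    inner_join(as_tibble(parch_mod) |>
                 select(chain_mod = "chain", resno_mod = "resno",
                        pv_mod = "pv_mean"),
               by = c("chain_mod", "resno_mod")) |>
    mutate(delta = .data$pv_mod - .data$pv_unmod,
           class = classify_delta(.data$delta, params$delta_threshold))
  site_row <- paired |>
    filter(.data$chain_unmod == site$chain, .data$resno_unmod == site$resno)
  if (nrow(site_row) != 1) {
    abort(sprintf("site %s:%d is not present in the mapping and profiles",
                  site$chain, site$resno))
  }
  nb_keys <- res_key(neighborhood$chain, neighborhood$resno)
  nb <- paired |>
    filter(res_key(.data$chain_unmod, .data$resno_unmod) %in% nb_keys)
  missing_nb <- setdiff(nb_keys, res_key(nb$chain_unmod, nb$resno_unmod))
  if (length(missing_nb) > 0) {
    abort(paste0("neighborhood residues missing from mapping/profiles: ",
                 paste(missing_nb, collapse = ", ")))
  }
  neighbors <- nb |>
    select(chain = "chain_unmod", resno = "resno_unmod",
           resname_unmod = "resname_unmod", resname_mod = "resname_mod",
           "pv_unmod", "pv_mod", "delta", "class") |>
    arrange(.data$chain, .data$resno)
  cum <- if (params$cumulative_mode == "filtered") {
    sum(neighbors$delta[abs(neighbors$delta) > params$delta_threshold])
  } else {
    sum(neighbors$delta)
  }
  wil <- if (nrow(neighbors) == 0) {
    structure(list(statistic = 0, w_plus = 0, w_minus = 0, n_effective = 0L,
                   p_value = 1, method = "degenerate", verdict = "ns",
                   degenerate = TRUE),
              class = "parch_wilcoxon")
  } else {
    wilcoxon_signed_rank(neighbors$pv_unmod, neighbors$pv_mod,
                         alpha = params$alpha)
  }
  out <- list(
    site = site_row |>
      select(chain = "chain_unmod", resno = "resno_unmod",
             resname_unmod = "resname_unmod", resname_mod = "resname_mod",
             "pv_unmod", "pv_mod", "delta", "class"),
    site_delta = site_row$delta,
    site_class = site_row$class,
    neighbors = neighbors,
    cumulative_delta = cum,
    wilcoxon = wil,
    params = params
  )
  class(out) <- "parch_delta"
  out
}

#' @export
print.parch_delta <- function(x, ...) {
  cat(sprintf(
    "<parch_delta> site %s:%d %s->%s | PV %0.2f -> %0.2f (delta %+0.2f, %s)\n",
    x$site$chain, x$site$resno, x$site$resname_unmod, x$site$resname_mod,
    x$site$pv_unmod, x$site$pv_mod, x$site_delta, x$site_class
  ))
  cat(sprintf("  %d neighbors within %g nm, cumulative delta %+0.2f (%s)\n",
              nrow(x$neighbors), x$params$neighbor_cutoff,
              x$cumulative_delta, x$params$cumulative_mode))
  print(x$wilcoxon)
  invisible(x)
}
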