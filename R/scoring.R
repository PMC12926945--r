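# PARCH scoring: turn a residue's water-retention profile over the heating
# ramp into a 0-10 hydropathy value (0 hydrophobic, 10 hydrophilic), then
# aggregate replicates. The default scorer is the retention ratio --
# mean contacts in the final window of the ramp over mean contacts in the
# initial window, scaled to 0-10 -- implemented behind a pluggable
# scoring-strategy interface.

#' Retention-ratio PARCH scorer
#'
#' Returns a scoring function mapping a per-frame contact-count vector to a
#' PARCH value: `10 * clamp(mean(final window) / mean(initial window), 0, 1)`.
#' A residue whose initial window has zero contacts (buried, never hydrated)
#' scores 0 with `buried = TRUE`.
#'
#' @param w_init,w_final Fractions (0, 0.5] of the profile used as the
#'   initial and final windows (defaults 0.05 each).
#' @return A function of `(counts, temperature)` returning
#'   `list(pv, buried)`.
#' @export
retention_ratio_scorer <- function(w_init = 0.05, w_final = 0.05) {
  stopifnot(w_init > 0, w_init <= 0.5, w_final > 0, w_final <= 0.5)
  function(counts, temperature = NULL) {
    n <- length(counts)
    if (n == 0) abort("empty profile")
    ni <- max(1L, ceiling(w_init * n))
    nf <- max(1L, ceiling(w_final * n))
    m_init <- mean(counts[seq_len(ni)])
    m_final <- mean(counts[seq.int(n - nf + 1L, n)])
    if (m_init == 0) {
      list(pv = 0, buried = TRUE)
    } else {
      list(pv = 10 * clamp(m_final / m_init, 0, 1), buried = FALSE)
    }
  }
}

#' Evaporation-temperature PARCH scorer
#'
#' Alternative scoring strategy: the PARCH value is the position, within the
#' ramp, of the temperature at which the residue's contact count first drops
#' to half its initial-window mean, scaled to 0-10. Residues that never
#' lose half their water score 10; never-hydrated residues score 0
#' (`buried = TRUE`).
#'
#' @param w_init Initial-window fraction used for the reference count.
#' @return A scoring function, as for [retention_ratio_scorer()].
#' @export
escape_temperature_scorer <- function(w_init = 0.05) {
  function(counts, temperature) {
    n <- length(counts)
    ni <- max(1L, ceiling(w_init * n))
    m_init <- mean(counts[seq_len(ni)])
    if (m_init == 0) return(list(pv = 0, buried = TRUE))
    below <- which(counts <= m_init / 2)
    if (length(below) == 0) return(list(pv = 10, buried = FALSE))
    t_half <- temperature[below[1]]
    frac <- (t_half - temperature[1]) /
      (temperature[n] - temperature[1])
    list(pv = 10 * clamp(frac, 0, 1), buried = FALSE)
  }
}

#' PARCH value from a single evaporation profile
#'
#' Convenience wrapper applying the retention-ratio rule to one count
#' vector.
#'
#' @param counts Per-frame contact counts, ramp-ordered.
#' @param w_init,w_final Window fractions, see [retention_ratio_scorer()].
#' @return Numeric PARCH value in `[0, 10]`, with attribute `buried`.
#' @examples
#' parch_from_profile(c(8, 8, 6, 4, 4))  # initial 8, final 4 -> 5
#' @export
parch_from_profile <- function(counts, w_init = 0.05, w_final = 0.05) {
  r <- retention_ratio_scorer(w_init, w_final)(counts)
  structure(r$pv, buried = r$buried)
}

#' Score one replicate's evaporation profiles
#'
#' @param profiles Long profile tibble from [build_profiles()].
#' @param scorer Scoring strategy, default [retention_ratio_scorer()].
#' @return Tibble with one row per residue: `chain`, `resno`, `resname`,
#'   `pv`, `buried`.
#' @export
score_profiles <- function(profiles, scorer = retention_ratio_scorer()) {
  profiles |>
    arrange(.data$chain, .data$resno, .data$frame) |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(
      score = list(scorer(.data$n_contacts, .data$temperature_k)),
      .groups = "drop"
    ) |>
    mutate(
      pv = map_dbl(.data$score, "pv"),
      buried = purrr::map_lgl(.data$score, "buried")
    ) |>
    select(-"score")
}

#' Aggregate replicate PARCH values into a profile
#'
#' Computes per-residue mean and sample standard deviation of the PARCH
#' value across independent annealing replicates (the protocol uses
#' quintuplicates).
#'
#' @param replicate_scores Tibble stacking per-replicate outputs of
#'   [score_profiles()] with an added `replicate` column, or a list of such
#'   per-replicate tibbles.
#' @return A `parch_profile` tibble: `chain`, `resno`, `resname`,
#'   `pv_mean`, `pv_sd` (NA for a single replicate), `n_rep`, `buried`
#'   (TRUE when every replicate found the residue never hydrated).
#' @export
aggregate_replicates <- function(replicate_scores) {
  if (is.list(replicate_scores) && !is.data.frame(replicate_scores)) {
    replicate_scores <- bind_rows(replicate_scores, .id = "replicate")
  }
  if (!"replicate" %in% names(replicate_scores)) {
    replicate_scores$replicate <- 1L
  }
  keys <- replicate_scores |>
    group_by(.data$replicate) |>
    summarise(k = paste(sort(res_key(.data$chain, .data$resno)),
                        collapse = "|"), .groups = "drop")
  if (length(unique(keys$k)) != 1L) {
    abort("replicates do not cover the same residue keys")
  }
  out <- replicate_scores |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(
      pv_mean = mean(.data$pv),
      pv_sd = if (n() > 1) sd(.data$pv) else NA_real_,
      n_rep = n(),
      buried = all(.data$buried),
      .groups = "drop"
    ) |>
    arrange(.data$chain, .data$resno)
  class(out) <- c("parch_profile", class(out))
  out
}

#' Score annealing replicates end to end
#'
#' Runs [build_profiles()] + [score_profiles()] on each replicate
#' trajectory and aggregates the per-residue PARCH values.
#'
#' @param structure A `parch_structure`.
#' @param trajectories A `parch_trajectory` or list of replicate
#'   trajectories.
#' @param schedule An [annealing_schedule()].
#' @param params A [contact_params()].
#' @param scorer Scoring strategy, default [retention_ratio_scorer()].
#' @param time_offset Equilibration carry-over to drop (ps).
#' @return A `parch_profile` tibble, see [aggregate_replicates()].
#' @export
score_trajectories <- function(structure, trajectories,
                               schedule = annealing_schedule(),
                               params = contact_params(),
                               scorer = retention_ratio_scorer(),
                               time_offset = 0) {
  if (inherits(trajectories, "parch_trajectory")) {
    trajectories <- list(trajectories)
  }
  per_rep <- imap(trajectories, function(traj, i) {
    build_profiles(traj, structure, schedule, params, time_offset) |>
      score_profiles(scorer) |>
      mutate(replicate = as.integer(i))
  })
  aggregate_replicates(bind_rows(per_rep))
}

#' Read/write a PARCH profile TSV
#'
#' Tab-separated profile with columns `chain`, `resno`, `resname`,
#' `pv_mean`, `pv_sd`, `n_rep`, `buried`.
#'
#' @param profile A `parch_profile` tibble.
#' @param path File path.
#' @return `write_parch_profile()` returns `path` invisibly;
#'   `read_parch_profile()` returns a `parch_profile` tibble.
#' @export
write_parch_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}

#' @rdname write_parch_profile
#' @export
read_parch_profile <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chain = readr::col_character(), resno = readr::col_integer(),
      resname = readr::col_character(), pv_mean = readr::col_double(),
      pv_sd = readr::col_double(), n_rep = readr::col_integer(),
      buried = readr::col_logical()
    )
  )
  class(out) <- c("parch_profile", class(out))
  out
}
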