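#' Specification of a synthetic two-group EEG cohort
#'
#' Describes everything needed to generate, reproducibly, a cohort of
#' 4-channel sleep-EEG-like recordings in which inter-channel correlation
#' is band-specific and differs between an "OSA-like" and a
#' "healthy-like" group.  Coupling is induced per band by Cholesky mixing
#' of independent band-limited noises; each subject's per-band coupling
#' is drawn uniformly from the group's range, and an independent pink
#' (1/f power) noise floor is added per channel so that the filtering and
#' decomposition stages are non-trivial.
#'
#' The default `"osa_contrast"` preset carries strong delta-band
#' coupling in the OSA-like group (uniform in 0.75-0.90) against weaker
#' coupling in the healthy-like group (0.45-0.65), with all other bands
#' identical across groups.
#'
#' @param n_osa,n_healthy subjects per group (defaults 40 and 10, the
#'   conventional OSA-heavy clinical split).
#' @param fs sampling rate, Hz (default 200).
#' @param duration_s recording length per subject, seconds (default 300).
#' @param channel_labels four channel names (default the ISRUC
#'   derivations F4-A1, F3-A2, O1-A2, O2-A1).
#' @param coupling named list: for each band, a list with elements `osa`
#'   and `healthy`, each a length-2 range (or single value) from which
#'   the subject's common inter-channel correlation is drawn.
#' @param band_powers named numeric vector of relative band variances
#'   (fractions of the structured, non-floor variance; normalized to 1).
#' @param pink_floor fraction of total per-channel variance carried by
#'   the independent 1/f noise floor (default 0.2).
#' @param bands band edge table, default [eeg_bands()].
#' @param seed root seed; per-subject streams are derived by stable
#'   hashing of (seed, group, index), so cohorts are extensible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_osa = 40, n_healthy = 10, fs = 200,
                        duration_s = 300,
                        channel_labels = c("F4-A1", "F3-A2", "O1-A2", "O2-A1"),
                        coupling = preset_coupling("osa_contrast"),
                        band_powers = c(delta = 0.40, theta = 0.20,
                                        alpha = 0.15, beta = 0.15,
                                        gamma = 0.10),
                        pink_floor = 0.2, bands = eeg_bands(), seed = 1L) {
  stopifnot(n_osa >= 0, n_healthy >= 0, fs > 0, duration_s > 0,
            pink_floor >= 0, pink_floor < 1)
  check_bands(bands)
  missing_b <- setdiff(names(coupling), as.character(bands$band))
  if (length(missing_b)) {
    abort(sprintf("Coupling given for unknown band(s): %s",
                  paste(missing_b, collapse = ", ")))
  }
  band_powers <- band_powers[names(band_powers) %in% as.character(bands$band)]
  band_powers <- band_powers / sum(band_powers)
  structure(
    list(n_osa = as.integer(n_osa), n_healthy = as.integer(n_healthy),
         fs = fs, duration_s = duration_s,
         channel_labels = channel_labels, coupling = coupling,
         band_powers = band_powers, pink_floor = pink_floor,
         bands = bands, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @param name preset name; `"osa_contrast"` is the delta-coupling
#'   group contrast described above.
#' @export
preset_coupling <- function(name = "osa_contrast") {
  if (!identical(name, "osa_contrast")) {
    abort(sprintf("Unknown preset '%s'.", name))
  }
  list(
    delta = list(osa = c(0.75, 0.90), healthy = c(0.45, 0.65)),
    theta = list(osa = c(0.30, 0.40), healthy = c(0.30, 0.40)),
    alpha = list(osa = c(0.30, 0.40), healthy = c(0.30, 0.40)),
    beta  = list(osa = c(0.40, 0.50), healthy = c(0.40, 0.50)),
    gamma = list(osa = c(0.20, 0.30), healthy = c(0.20, 0.30))
  )
}

# Deterministic per-(seed, group, index) stream seed, kept below 2^31.
derive_seed <- function(seed, group, index) {
  g <- if (toupper(group) == "OSA") 1L else 2L
  as.integer((as.double(seed) * 1000003 + g * 999983 + index * 101) %%
               2147483647)
}

#' Band-limited unit-variance noise
#'
#' White Gaussian noise whose Fourier coefficients outside
#' `[f_low, f_high]` are zeroed, then renormalized to zero mean and unit
#' variance.  By construction the out-of-band power is (numerically)
#' zero.
#'
#' @param f_low,f_high band edges, Hz; must lie inside `(0, fs/2)`.
#' @param fs sampling rate, Hz.
#' @param n number of samples.
#' @param seed integer stream seed (same seed, same vector).
#' @return Numeric vector of length `n`.
#' @export
band_limited_noise <- function(f_low, f_high, fs, n, seed) {
  if (!(f_low > 0 && f_low < f_high && f_high <= fs / 2)) {
    abort(sprintf("Band [%g, %g] Hz outside (0, %g] Hz.", f_low, f_high, fs / 2))
  }
  withr::with_seed(seed, {
    x <- rnorm(n)
    spec <- fft(x)
    f <- seq(0, n - 1) * fs / n
    f <- pmin(f, fs - f)  # two-sided frequency axis
    spec[f < f_low | f > f_high] <- 0
    y <- Re(fft(spec, inverse = TRUE)) / n
    y <- y - mean(y)
    s <- sd(y)
    if (s == 0) abort("Degenerate band: no Fourier bin inside the band.")
    y / s
  })
}

# Pink (1/f power) noise: white spectrum shaped by 1/sqrt(f) above f_min,
# zero below; unit variance.
pink_noise <- function(fs, n, seed, f_min = 0.5) {
  withr::with_seed(seed, {
    spec <- fft(rnorm(n))
    f <- seq(0, n - 1) * fs / n
    f <- pmin(f, fs - f)
    shape <- ifelse(f >= f_min, 1 / sqrt(f), 0)
    y <- Re(fft(spec * shape, inverse = TRUE)) / n
    y <- y - mean(y)
    y / sd(y)
  })
}

#' Channels with a prescribed correlation structure
#'
#' Mixes independent band-limited noises with the Cholesky factor of the
#' target correlation matrix, so the returned channels' empirical
#' correlation converges to the target as `n` grows.
#'
#' @param target_r symmetric positive-semidefinite correlation matrix
#'   with unit diagonal (one row per channel).
#' @param f_low,f_high band edges, Hz.
#' @param fs sampling rate, Hz.
#' @param n samples.
#' @param seed integer stream seed.
#' @return A `nrow(target_r)` x `n` matrix.
#' @export
coupled_channels <- function(target_r, f_low, f_high, fs, n, seed) {
  target_r <- as.matrix(target_r)
  if (!isTRUE(all.equal(target_r, t(target_r))) ||
      any(abs(diag(target_r) - 1) > 1e-10)) {
    abort("`target_r` must be symmetric with unit diagonal.")
  }
  ev <- eigen(target_r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort(sprintf("`target_r` is not positive semidefinite (smallest eigenvalue %.4g).",
                  min(ev)))
  }
  k <- nrow(target_r)
  u <- t(vapply(seq_len(k), function(i) {
    band_limited_noise(f_low, f_high, fs, n, seed + i - 1L)
  }, numeric(n)))
  # chol of a PSD (possibly singular) matrix via tiny ridge
  L <- t(chol(target_r + diag(1e-12, k)))
  L %*% u
}

equicorrelation <- function(k, r) {
  m <- matrix(r, k, k)
  diag(m) <- 1
  m
}

#' Generate one synthetic subject
#'
#' The recording is the sum over bands of
#' `sqrt(band power) * coupled_channels(band)` plus an independent pink
#' noise floor per channel, deterministic in `(spec$seed, group, index)`.
#'
#' @param spec a [cohort_spec()].
#' @param group `"OSA"` or `"HEALTHY"`.
#' @param index 1-based subject index within the group.
#' @return A `synthetic_subject`: the [eeg_recording()] in `$recording`
#'   plus `$coupling`, the per-band ground-truth inter-channel
#'   correlation used.
#' @export
generate_subject <- function(spec, group = c("OSA", "HEALTHY"), index = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(toupper(group[1]), c("OSA", "HEALTHY"))
  n <- round(spec$fs * spec$duration_s)
  k <- length(spec$channel_labels)
  sseed <- derive_seed(spec$seed, group, index)
  gkey <- if (group == "OSA") "osa" else "healthy"

  # per-subject ground-truth coupling draws (one stream, then signals)
  truth <- withr::with_seed(sseed, {
    vapply(names(spec$coupling), function(b) {
      rng <- spec$coupling[[b]][[gkey]]
      if (length(rng) == 1) rng else runif(1, rng[1], rng[2])
    }, numeric(1))
  })

  dat <- matrix(0, k, n)
  bi <- 0L
  for (b in names(spec$band_powers)) {
    bi <- bi + 1L
    pw <- spec$band_powers[[b]]
    if (pw <= 0) next
    row <- spec$bands[as.character(spec$bands$band) == b, ]
    r <- if (b %in% names(truth)) truth[[b]] else 0
    ch <- coupled_channels(equicorrelation(k, r), row$f_low, row$f_high,
                           spec$fs, n, seed = sseed + 1000L * bi)
    dat <- dat + sqrt(pw * (1 - spec$pink_floor)) * ch
  }
  if (spec$pink_floor > 0) {
    for (i in seq_len(k)) {
      dat[i, ] <- dat[i, ] + sqrt(spec$pink_floor) *
        pink_noise(spec$fs, n, seed = sseed + 100000L + i)
    }
  }
  rec <- eeg_recording(dat, spec$channel_labels, spec$fs,
                       subject_id = sprintf("%s_%03d", tolower(group), index),
                       group_label = group)
  structure(list(recording = rec, group = group, index = index,
                 coupling = truth, seed = sseed),
            class = "synthetic_subject")
}

#' Generate a whole synthetic cohort
#'
#' @param spec a [cohort_spec()]; both group sizes must be positive.
#' @param dir optional output directory: each subject is written in the
#'   columnar text format and a `manifest.json` (subject id, group,
#'   ground-truth couplings, seeds) makes the run fully reproducible.
#'   Existing subject files are treated as path collisions and rejected.
#' @return A list with `subjects` (list of `synthetic_subject`) and
#'   `manifest` (tibble: `subject_id`, `group`, `index`, `seed`, one
#'   `coupling_<band>` column per band).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_osa < 1 || spec$n_healthy < 1) {
    abort("Both groups need at least one subject.")
  }
  subs <- c(
    lapply(seq_len(spec$n_osa), function(i) generate_subject(spec, "OSA", i)),
    lapply(seq_len(spec$n_healthy),
           function(i) generate_subject(spec, "HEALTHY", i))
  )
  manifest <- purrr::map_dfr(subs, function(s) {
    cp <- as.list(s$coupling)
    names(cp) <- paste0("coupling_", names(cp))
    dplyr::bind_cols(
      tibble(subject_id = s$recording$subject_id, group = s$group,
             index = s$index, seed = s$seed),
      tibble::as_tibble(cp)
    )
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(manifest$subject_id, ".tsv"))
    if (any(file.exists(paths))) {
      abort(sprintf("Output collision: %s already exists.",
                    paths[file.exists(paths)][1]))
    }
    for (i in seq_along(subs)) write_columnar(subs[[i]]$recording, paths[i])
    jsonlite::write_json(
      list(root_seed = spec$seed, fs = spec$fs,
           duration_s = spec$duration_s, pink_floor = spec$pink_floor,
           band_powers = as.list(spec$band_powers),
           subjects = manifest),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(subjects = subs, manifest = manifest)
}
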