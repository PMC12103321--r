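#' Total organic carbon from TC and TIC
#'
#' `TOC = TC - TIC`. A negative difference is physically impossible and
#' signals a measurement problem; it is returned unchanged but flagged
#' (attribute `negative`) with a warning.
#'
#' @param tc,tic Total and total inorganic carbon, mg C/L. Vectorised.
#' @return TOC, mg C/L, with logical attribute `negative`.
#' @examples
#' toc_from_tc_tic(5.0, 1.2)  # 3.8
#' @export
toc_from_tc_tic <- function(tc, tic) {
  if (any(tc < 0) || any(tic < 0)) stop("TC and TIC must be non-negative")
  toc <- tc - tic
  neg <- toc < 0
  if (any(neg))
    warning("negative TOC (TIC > TC): physically impossible, check measurement")
  structure(toc, negative = neg)
}

# Sample coefficient of variation in percent (n-1 denominator).
# Identical readings (including all-zero blanks) have CV 0 by convention.
.cv_pct <- function(x) {
  if (stats::sd(x) == 0) return(0)
  100 * stats::sd(x) / mean(x)
}

#' Replicate acceptance rule of the TOC analyzer
#'
#' Mirrors the instrument's software: two replicates are measured; if their
#' coefficient of variation exceeds `cv_threshold` a third is required, and
#' the accepted value is the mean of the two closest replicates (the third
#' is rejected). CV uses the sample (n-1) standard deviation over the mean,
#' in percent. When the third replicate is equidistant from both of the
#' first two, the first two are kept (deterministic tie-break).
#'
#' @param values Numeric vector of 2 or 3 replicate readings, mg/L.
#' @param cv_threshold CV acceptance threshold, percent (default 2).
#' @param channel Optional channel label (`"TC"` or `"TIC"`).
#' @return Object of class `measurement_record`: `replicate_values`,
#'   `accepted_value` (mean of the two used replicates; `NA` when a third
#'   replicate is needed but absent), `used` (indices), `rejected_index`,
#'   `cv_first_two` (%), `needs_third` (logical).
#' @examples
#' accept_replicates(c(5.00, 5.02))
#' accept_replicates(c(5.0, 5.4, 5.05))  # accepts mean(5.0, 5.05)
#' @export
accept_replicates <- function(values, cv_threshold = 2, channel = NA_character_) {
  if (!length(values) %in% 2:3) stop("need 2 or 3 replicate values")
  if (any(values < 0)) stop("replicate values must be non-negative")
  cv12 <- .cv_pct(values[1:2])
  if (cv12 <= cv_threshold) {
    used <- 1:2
    rejected <- if (length(values) == 3L) 3L else NA_integer_
    accepted <- mean(values[1:2])
    needs_third <- FALSE
  } else if (length(values) == 2L) {
    used <- integer(0)
    rejected <- NA_integer_
    accepted <- NA_real_
    needs_third <- TRUE
  } else {
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    gaps <- vapply(pairs, function(p) abs(diff(values[p])), numeric(1))
    # tie-break: a third replicate equidistant from both of the first two
    # gives no closest pair — keep the first two (deterministic).
    used <- if (gaps[2] == gaps[3]) pairs[[1L]] else pairs[[which.min(gaps)]]
    rejected <- setdiff(1:3, used)
    accepted <- mean(values[used])
    needs_third <- FALSE
  }
  structure(list(channel = channel, replicate_values = values,
                 accepted_value = accepted, used = used,
                 rejected_index = rejected, cv_first_two = cv12,
                 cv_threshold = cv_threshold, needs_third = needs_third),
            class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  if (x$needs_third) {
    cat(sprintf("<measurement_record> CV %.2f%% > %.2g%%: third replicate required\n",
                x$cv_first_two, x$cv_threshold))
  } else {
    cat(sprintf("<measurement_record> accepted %.4g mg/L (replicates %s; CV12 %.2f%%)\n",
                x$accepted_value, paste(x$used, collapse = ","), x$cv_first_two))
  }
  invisible(x)
}

#' Injection-volume / calibration-range table of the analyzer
#'
#' The instrument's pairing of injection volume, concentration range and
#' calibration curve, for the standard (particles <= 10 um) and modified
#' (> 10 um, TC only) procedures.
#'
#' @return `data.frame` with columns `channel`, `procedure`, `volume_uL`,
#'   `range_lo`, `range_hi` (mg/L), `curve`.
#' @export
injection_plans <- function() {
  data.frame(
    channel   = c("TC", "TC", "TC", "TIC", "TIC", "TC"),
    procedure = c("standard", "standard", "standard", "standard", "standard",
                  "modified"),
    volume_uL = c(2000, 408, 50, 2000, 130, 500),
    range_lo  = c(0.01, 0.1, 1.0, 0.02, 0.2, 1.0),
    range_hi  = c(0.1, 1.0, 10.0, 0.2, 5.0, 50.0),
    curve     = c("TC Curve 1", "TC Curve 2", "TC Curve 3",
                  "TIC Curve 1", "TIC Curve 2", "TC Curve 4"),
    stringsAsFactors = FALSE
  )
}

#' Select the injection plan for an estimated carbon concentration
#'
#' Picks the analyzer's (volume, calibration range) row for the estimated
#' concentration and channel. Particles above 10 um switch the TC channel to
#' the modified procedure (fixed 500 uL, range extended to 50 mg/L). A
#' concentration outside every range yields a dilution-required plan with a
#' suggested gravimetric dilution factor targeting 5 mg/L (rounded up to one
#' decimal).
#'
#' @param estimated_concentration Estimated carbon concentration, mg/L.
#' @param channel `"TC"` or `"TIC"`.
#' @param particle_size_um Particle diameter, um (drives the > 10 um rule).
#' @return Object of class `injection_plan`: `channel`, `procedure`,
#'   `volume_uL`, `curve`, `range` (lo, hi), `dilution_required`,
#'   `dilution_factor`.
#' @examples
#' select_injection_plan(5, "TC", 1)    # 50 uL, TC Curve 3
#' select_injection_plan(25, "TC", 90)  # 500 uL, modified
#' @export
select_injection_plan <- function(estimated_concentration,
                                  channel = c("TC", "TIC"),
                                  particle_size_um = 1) {
  channel <- match.arg(channel)
  if (estimated_concentration <= 0) stop("estimated concentration must be positive")
  tab <- injection_plans()
  proc <- if (channel == "TC" && particle_size_um > 10) "modified" else "standard"
  rows <- tab[tab$channel == channel & tab$procedure == proc, ]
  hit <- rows[rows$range_lo <= estimated_concentration &
                estimated_concentration <= rows$range_hi, ]
  if (nrow(hit) >= 1L) {
    hit <- hit[which.min(hit$volume_uL * 0 + seq_len(nrow(hit))), ]  # first match
    plan <- list(channel = channel, procedure = proc,
                 volume_uL = hit$volume_uL, curve = hit$curve,
                 range = c(hit$range_lo, hit$range_hi),
                 dilution_required = FALSE, dilution_factor = 1)
  } else {
    # Outside all ranges: gravimetric dilution aiming for 5 mg/L (TC Curve 3).
    fac <- ceiling(10 * estimated_concentration / 5) / 10
    target <- rows[rows$range_lo <= 5 & 5 <= rows$range_hi, ][1, ]
    plan <- list(channel = channel, procedure = proc,
                 volume_uL = target$volume_uL, curve = target$curve,
                 range = c(target$range_lo, target$range_hi),
                 dilution_required = TRUE, dilution_factor = fac)
  }
  structure(plan, class = "injection_plan")
}

#' @export
print.injection_plan <- function(x, ...) {
  cat(sprintf("<injection_plan> %s %s: %g uL, %s, range %g-%g mg/L%s\n",
              x$channel, x$procedure, x$volume_uL, x$curve,
              x$range[1], x$range[2],
              if (x$dilution_required)
                sprintf(" (dilute %gx to ~5 mg/L first)", x$dilution_factor)
              else ""))
  invisible(x)
}

# Round half away from zero, as used for displayed particle counts.
.round_half_up <- function(x) floor(x + 0.5)

#' Expected number of particles in one injection
#'
#' Injected carbon mass over carbon mass per particle:
#' `count = (tc * volume) / ((pi/6) d^3 rho_p w_C)`.
#'
#' @param target_tc Carbon concentration aimed for, mg C/L.
#' @param injection_volume Injection volume, uL.
#' @param particle A [particle_spec()] whose polymer has a carbon fraction.
#' @return List with `expected` (real count) and `rounded` (half-up integer,
#'   as displayed).
#' @examples
#' ps30 <- particle_spec(30, "um", polymer = get_polymer("PS"))
#' expected_particles_injected(5, 50, ps30)  # ~18.3 -> 18
#' @export
expected_particles_injected <- function(target_tc, injection_volume, particle) {
  if (is.null(particle$polymer))
    stop("particle needs a polymer reference for carbon arithmetic")
  w_c <- particle$polymer$carbon_fraction
  if (w_c <= 0) stop("polymer carbon fraction must be positive")
  if (target_tc <= 0 || injection_volume <= 0)
    stop("target TC and injection volume must be positive")
  carbon_injected_mg <- target_tc * injection_volume * 1e-6        # mg C
  vol_cm3 <- pi / 6 * (particle$diameter * 100)^3                  # cm3
  carbon_per_particle_mg <- vol_cm3 * particle$density * 1000 * w_c
  expected <- carbon_injected_mg / carbon_per_particle_mg
  list(expected = expected, rounded = .round_half_up(expected))
}

#' Poisson distribution of the injected particle count
#'
#' With particles homogeneously suspended, the number entering one injection
#' is Poisson with mean equal to the expected count. The support is truncated
#' adaptively so the returned probabilities sum to 1 within 1e-9.
#'
#' @param expected_count Mean count (>= 0).
#' @return `data.frame` with columns `count` and `probability`.
#' @examples
#' pmf <- injection_count_distribution(0.676)
#' pmf$probability[pmf$count == 0]  # ~0.51: a near 50/50 chance of zero
#' @export
injection_count_distribution <- function(expected_count) {
  if (expected_count < 0) stop("expected count must be non-negative")
  if (expected_count == 0)
    return(data.frame(count = 0L, probability = 1))
  kmax <- stats::qpois(1e-12, expected_count, lower.tail = FALSE)
  k <- 0:kmax
  data.frame(count = k, probability = stats::dpois(k, expected_count))
}

#' Recommend standard or modified TOC procedure for a particle
#'
#' Applies the size rule (modified strictly above 10 um; at exactly 10 um
#' both procedures work and the standard one is recommended) and attaches
#' the rationale: expected injected counts under both plans and the
#' gravitational settling speed.
#'
#' @param particle A [particle_spec()] with polymer reference.
#' @param fluid A [fluid_spec()].
#' @param standard_target_tc,modified_target_tc Carbon concentrations aimed
#'   for by the two procedures, mg C/L (defaults 5 and 25).
#' @return List: `procedure`, `diameter_um`, `size_rule`,
#'   `expected_count_standard`, `expected_count_modified`,
#'   `settling_speed_cm_min`.
#' @export
recommend_procedure <- function(particle, fluid = water_20C(),
                                standard_target_tc = 5,
                                modified_target_tc = 25) {
  d_um <- particle$diameter * 1e6
  proc <- if (d_um > 10) "modified" else "standard"
  list(
    procedure = proc,
    diameter_um = d_um,
    size_rule = sprintf("modified procedure for diameters > 10 um (d = %g um)", d_um),
    expected_count_standard =
      expected_particles_injected(standard_target_tc, 50, particle)$expected,
    expected_count_modified =
      expected_particles_injected(modified_target_tc, 500, particle)$expected,
    settling_speed_cm_min = stokes_settling_speed(particle, fluid)
  )
}

#' Read a replicate stream CSV
#'
#' Expected columns: `sample_id`, `channel`, `replicate_no`, `value_mg_L`.
#'
#' @param path CSV file path.
#' @return `data.frame` with those columns.
#' @export
read_replicate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "channel", "replicate_no", "value_mg_L")
  if (!all(need %in% names(df)))
    stop("replicate CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Reduce a replicate table to accepted TC/TIC and TOC values
#'
#' Applies [accept_replicates()] per sample and channel, then forms
#' `TOC = TC - TIC` where both channels are present.
#'
#' @param df `data.frame` as from [read_replicate_csv()].
#' @param cv_threshold CV threshold, percent.
#' @return `data.frame` with one row per sample: `sample_id`, `TC`, `TIC`,
#'   `TOC` (mg/L; `NA` where a channel is missing or needs a third
#'   replicate).
#' @export
reduce_replicate_table <- function(df, cv_threshold = 2) {
  samples <- unique(df$sample_id)
  out <- lapply(samples, function(s) {
    get_ch <- function(ch) {
      v <- df$value_mg_L[df$sample_id == s & df$channel == ch]
      v <- v[order(df$replicate_no[df$sample_id == s & df$channel == ch])]
      if (length(v) == 0L) return(NA_real_)
      accept_replicates(v, cv_threshold, channel = ch)$accepted_value
    }
    tc <- get_ch("TC"); tic <- get_ch("TIC")
    toc <- if (is.na(tc) || is.na(tic)) NA_real_
           else suppressWarnings(as.numeric(toc_from_tc_tic(tc, tic)))
    data.frame(sample_id = s, TC = tc, TIC = tic, TOC = toc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
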