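#' Pair rectal temperatures with the closest surface-temperature values
#'
#' Each rectal measurement is matched, per measurement type, to the defined
#' hourly value closest in time. The hour that contains the rectal timestamp
#' is preferred when its value is defined; otherwise the nearest defined
#' hour is used, with ties broken toward the earlier hour (the value already
#' available at pairing time). Pairs farther apart than `max_gap_min`
#' minutes are dropped. A calf with no defined values for a measurement
#' contributes no pairs for it.
#'
#' @param rectal data.frame `calf_id`, `timestamp`, `rectal_temp_c`.
#' @param transforms output of [st_transforms()] (the four hourly
#'   measurements), or a single `hourly_series`.
#' @param max_gap_min maximum allowed |rectal time - hour| in minutes.
#' @return data.frame `calf_id`, `rectal_time`, `rectal_temp_c`,
#'   `measurement`, `value`, `time_gap_min` - one row per retained rectal
#'   observation x measurement type.
#' @export
pair_rectal <- function(rectal, transforms, max_gap_min = 60) {
  if (inherits(transforms, "hourly_series")) {
    role <- value_role(transforms)
    cols <- stats::setNames(list(transforms$value), role)
    base <- data.frame(calf_id = transforms$calf_id, hour = transforms$hour)
  } else {
    cols <- as.list(transforms[, c("raw", "estimated_st", "rst",
                                   "estimated_rst")])
    base <- transforms[, c("calf_id", "hour")]
  }

  out <- vector("list", length(cols))
  for (mi in seq_along(cols)) {
    measurement <- names(cols)[mi]
    vals <- cols[[mi]]
    rows <- lapply(unique(rectal$calf_id), function(id) {
      r <- rectal[rectal$calf_id == id, , drop = FALSE]
      sel <- base$calf_id == id & !is.na(vals)
      if (!any(sel)) return(NULL)
      hrs <- as.numeric(base$hour[sel])
      v <- vals[sel]
      t <- as.numeric(r$timestamp)
      pick <- integer(length(t)); gap <- numeric(length(t))
      for (j in seq_along(t)) {
        d <- abs(t[j] - hrs)
        contain <- which(hrs <= t[j] & t[j] < hrs + 3600)
        if (length(contain)) {
          pick[j] <- contain[1L]
        } else {
          best <- min(d)
          cand <- which(d == best)   # tie -> earlier hour
          pick[j] <- cand[1L]
        }
        gap[j] <- d[pick[j]] / 60
      }
      keep <- gap <= max_gap_min
      if (!any(keep)) return(NULL)
      data.frame(calf_id = id, rectal_time = r$timestamp[keep],
                 rectal_temp_c = r$rectal_temp_c[keep],
                 measurement = measurement, value = v[pick[keep]],
                 time_gap_min = gap[keep], stringsAsFactors = FALSE)
    })
    out[[mi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Association of rectal temperature with each surface-temperature measurement
#'
#' Ordinary least-squares regression of the rectal temperature on each
#' paired measurement; the coefficient of determination (R-squared) per
#' measurement type quantifies how well the measurement tracks the rectal
#' temperature. `adjust_calf = TRUE` adds calf indicator terms,
#' approximating a repeated-measures structure; the default reports the
#' simple regression's R-squared. A zero-variance measurement has no
#' defined R-squared and is reported as `NA`.
#'
#' @param pairs output of [pair_rectal()].
#' @param adjust_calf logical; include per-calf fixed effects.
#' @param common logical; restrict every measurement's regression to the
#'   rectal observations paired under *all* measurement types (default).
#'   The residual measurements are undefined during the first days of a
#'   trace, so without this restriction the R-squared values would be
#'   compared across different subsamples.
#' @return data.frame `measurement`, `n`, `r_squared`, sorted by decreasing
#'   R-squared.
#' @export
rectal_association <- function(pairs, adjust_calf = FALSE, common = TRUE) {
  if (common && length(unique(pairs$measurement)) > 1L) {
    obs_key <- paste(pairs$calf_id, as.numeric(pairs$rectal_time))
    counts <- table(obs_key)
    full <- names(counts)[counts == length(unique(pairs$measurement))]
    pairs <- pairs[obs_key %in% full, , drop = FALSE]
  }
  rows <- lapply(split(pairs, pairs$measurement), function(p) {
    n <- nrow(p)
    if (n < 3 || stats::var(p$value) == 0) {
      r2 <- NA_real_
    } else if (adjust_calf && length(unique(p$calf_id)) > 1) {
      fit <- stats::lm(rectal_temp_c ~ value + factor(calf_id), data = p)
      r2 <- summary(fit)$r.squared
    } else {
      fit <- stats::lm(rectal_temp_c ~ value, data = p)
      r2 <- summary(fit)$r.squared
    }
    data.frame(measurement = p$measurement[1L], n = n, r_squared = r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the rectal-association experiment end to end
#'
#' Simulates the comparison study (by default 34 calves for 7 days with
#' twice-daily rectal measurements), preprocesses the traces, computes the
#' four hourly measurements, pairs them with the rectal records and reports
#' the R-squared of each measurement against rectal temperature.
#'
#' @param config a [sim_config()]; defaults to the 34-calf / 7-day design.
#' @param max_gap_min pairing gap limit, minutes.
#' @param adjust_calf passed to [rectal_association()].
#' @return list with `pairs`, `association` (the R-squared table) and the
#'   simulated objects.
#' @export
run_rectal_experiment <- function(config = sim_config(n_calves = 34,
                                                      duration_days = 7),
                                  max_gap_min = 60, adjust_calf = FALSE) {
  sim <- simulate_calves(config)
  rectal <- simulate_rectal(config, sim$traces, sim$episodes)
  hourly <- preprocess_st(sim$traces)
  tf <- st_transforms(hourly)
  pairs <- pair_rectal(rectal, tf, max_gap_min)
  assoc <- rectal_association(pairs, adjust_calf)
  list(pairs = pairs, association = assoc, sim = sim, rectal = rectal,
       transforms = tf)
}
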