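#' Read or write a carrier metadata table
#'
#' Carrier metadata is a tab-separated table with columns `carrier_id`,
#' `organism`, `role_class` (one of `nif`, `non_nif_bacterial`, `plant`),
#' `potential_mv_1`, `potential_mv_2` (blank when the carrier has a single
#' midpoint potential, or two clusters at the same potential) and `activity`
#' (optional relative nitrogenase activity; blank allowed).
#'
#' @param path file path.
#' @return `read_carriers()` returns a data frame; `write_carriers()` is
#'   called for its side effect and returns `path` invisibly.
#' @export
read_carriers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("carrier_id", "organism", "role_class", "potential_mv_1")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("carrier table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$potential_mv_2)) df$potential_mv_2 <- NA_real_
  if (is.null(df$activity)) df$activity <- NA_real_
  bad <- setdiff(unique(df$role_class), c("nif", "non_nif_bacterial", "plant"))
  if (length(bad))
    stop("unknown role_class value(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$potential_mv_1)))
    stop("potential_mv_1 must be present for every carrier")
  df
}

#' @rdname read_carriers
#' @param carriers carrier data frame.
#' @export
write_carriers <- function(carriers, path) {
  utils::write.table(carriers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Effective midpoint potential of a carrier
#'
#' Carriers with two clusters at distinct potentials transfer through the
#' higher (less negative) one; that potential is used for rate calculations.
#'
#' @param potential_mv_1,potential_mv_2 midpoint potentials in mV;
#'   `potential_mv_2` may be `NA`.
#' @return The higher potential in mV (vectorised).
#' @export
effective_potential <- function(potential_mv_1, potential_mv_2 = NA_real_) {
  pmax(potential_mv_1, potential_mv_2, na.rm = TRUE)
}

#' Evaluate one carrier against the distance and rate thresholds
#'
#' Measures the edge-to-edge cofactor distance in each docking model of one
#' carrier (nearest ligand cofactor to the receptor \[4Fe-4S\] cluster),
#' averages over models, computes the tunneling rate at the mean distance
#' using the carrier's effective potential, and classifies: `compatible` when
#' mean R <= `distance_threshold` (10 angstroms, inclusive) and log10 rate >=
#' `rate_threshold_log10` (6, i.e. 10^6 s^-1); `incompatible` when neither
#' holds; `marginal` otherwise.  Per-model distances are retained because
#' some carriers dock bimodally; the mean of per-model rates is also emitted
#' alongside the rate at the mean distance.
#'
#' @param models list of `docked_complex` objects for the carrier (one per
#'   docking model).  Models without a ligand cofactor are skipped with a
#'   warning; if all are skipped an error is raised.
#' @param record one-row carrier data frame (see [read_carriers()]) or a list
#'   with the same fields.
#' @param params a [tunneling_params()] object.
#' @param acceptor_potential_mV Fe-protein midpoint potential (default -415).
#' @param distance_threshold,rate_threshold_log10 classification thresholds.
#' @return A `compatibility_call` object.
#' @export
evaluate_carrier <- function(models, record, params = tunneling_params(),
                             acceptor_potential_mV = -415,
                             distance_threshold = 10,
                             rate_threshold_log10 = 6) {
  stopifnot(length(models) >= 1L)
  per_model <- numeric(0)
  kinds <- character(0)
  for (m in models) {
    res <- tryCatch(nearest_ligand_cofactor(m), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("model %d skipped: %s", m$model_index,
                      conditionMessage(res)))
      next
    }
    per_model <- c(per_model, res$measurement$R)
    kinds <- c(kinds, res$measurement$ligand_cofactor_kind)
  }
  if (length(per_model) == 0L)
    stop("no usable docking model for carrier ", record$carrier_id)

  eff <- effective_potential(record$potential_mv_1,
                             if (is.null(record$potential_mv_2)) NA_real_
                             else record$potential_mv_2)
  mean_R <- mean(per_model)
  dg <- driving_force(eff, acceptor_potential_mV)
  at_mean <- log10_tunneling_rate(mean_R, dg, params)
  per_rates <- log10_tunneling_rate(per_model, dg, params)$log10_rate

  distance_pass <- mean_R <= distance_threshold
  rate_pass <- at_mean$log10_rate >= rate_threshold_log10
  verdict <- if (distance_pass && rate_pass) "compatible"
             else if (!distance_pass && !rate_pass) "incompatible"
             else "marginal"
  structure(
    list(carrier_id = record$carrier_id,
         role_class = record$role_class %||% NA_character_,
         per_model_R = per_model,
         ligand_cofactor_kinds = kinds,
         mean_R = mean_R,
         effective_potential_mV = eff,
         acceptor_potential_mV = acceptor_potential_mV,
         delta_g = dg,
         regime = at_mean$regime,
         log10_rate_at_mean_R = at_mean$log10_rate,
         mean_log10_rate_over_models = mean(per_rates),
         distance_pass = distance_pass,
         rate_pass = rate_pass,
         verdict = verdict),
    class = "compatibility_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.compatibility_call <- function(x, ...) {
  cat(sprintf("<compatibility_call> %s: mean R = %.2f A (%s), E = %g mV, log10 k = %.2f -> %s\n",
              x$carrier_id, x$mean_R,
              paste(sprintf("%.1f", x$per_model_R), collapse = "/"),
              x$effective_potential_mV, x$log10_rate_at_mean_R, x$verdict))
  invisible(x)
}

#' Summarise a cohort of compatibility calls by role class
#'
#' Tallies verdicts and summarises the distance and rate distributions
#' (median and quartiles, the box-plot convention) per carrier role class.
#'
#' @param calls list of `compatibility_call` objects.
#' @return A `cohort_summary`: list with `verdicts` (role x verdict counts)
#'   and `stats` (per-role n, median/q25/q75 of mean R and of log10 rate,
#'   fraction passing each threshold).  Empty input gives empty tables.
#' @export
classify_cohort <- function(calls) {
  if (length(calls) == 0L)
    return(structure(list(verdicts = table(character(0), character(0)),
                          stats = data.frame()), class = "cohort_summary"))
  role <- vapply(calls, function(x) x$role_class, "")
  verdict <- vapply(calls, function(x) x$verdict, "")
  R <- vapply(calls, function(x) x$mean_R, 0)
  lg <- vapply(calls, function(x) x$log10_rate_at_mean_R, 0)
  dpass <- vapply(calls, function(x) x$distance_pass, TRUE)
  rpass <- vapply(calls, function(x) x$rate_pass, TRUE)
  stats_one <- function(idx) {
    qR <- stats::quantile(R[idx], c(.25, .5, .75), names = FALSE, type = 7)
    ql <- stats::quantile(lg[idx], c(.25, .5, .75), names = FALSE, type = 7)
    data.frame(n = length(idx),
               R_q25 = qR[1], R_median = qR[2], R_q75 = qR[3],
               log10_rate_q25 = ql[1], log10_rate_median = ql[2],
               log10_rate_q75 = ql[3],
               frac_distance_pass = mean(dpass[idx]),
               frac_rate_pass = mean(rpass[idx]))
  }
  roles <- unique(role)
  st <- do.call(rbind, lapply(roles, function(r) {
    cbind(role_class = r, stats_one(which(role == r)))
  }))
  rownames(st) <- NULL
  structure(list(verdicts = table(role, verdict), stats = st),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  if (nrow(x$stats) == 0L) { cat("  (empty cohort)\n"); return(invisible(x)) }
  print(x$verdicts)
  print(x$stats, digits = 3)
  invisible(x)
}

#' Ordinary least-squares fit of nitrogenase activity on cofactor distance
#'
#' Fits `activity ~ mean_R` by OLS (through [stats::lm()]) and reports slope,
#' intercept and the coefficient of determination r^2 = 1 - SSres/SStot.
#' Constant activity yields r^2 = 0 by convention; constant distance is a
#' degenerate predictor and an error.
#'
#' @param mean_R numeric vector of mean cofactor distances (angstroms), or a
#'   data frame with columns `mean_R` and `activity`.
#' @param activity non-negative activities (ignored if `mean_R` is a data
#'   frame).
#' @return A `distance_activity_fit` with elements `n`, `slope`, `intercept`,
#'   `r_squared` and the underlying `lm` fit.
#' @examples
#' fit_distance_activity(c(10, 12, 14, 16), c(80, 60, 45, 20))
#' @export
fit_distance_activity <- function(mean_R, activity = NULL) {
  if (is.data.frame(mean_R)) {
    activity <- mean_R$activity
    mean_R <- mean_R$mean_R
  }
  keep <- is.finite(mean_R) & is.finite(activity)
  mean_R <- mean_R[keep]; activity <- activity[keep]
  if (length(mean_R) < 3L) stop("need at least 3 (distance, activity) pairs")
  if (any(activity < 0)) stop("activities must be non-negative")
  if (stats::sd(mean_R) == 0) stop("degenerate predictor: distances have zero variance")
  fit <- stats::lm(activity ~ mean_R)
  ss_tot <- sum((activity - mean(activity))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(n = length(mean_R),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, lm_fit = fit),
            class = "distance_activity_fit")
}

#' @export
print.distance_activity_fit <- function(x, ...) {
  cat(sprintf("<distance_activity_fit> n = %d: activity = %.3f %+.3f * R,  r^2 = %.3f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.distance_activity_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.distance_activity_fit <- function(object, mean_R, ...) {
  object$intercept + object$slope * mean_R
}

#' Assemble a machine-readable screening report
#'
#' Builds one deterministic report object per carrier (distances, effective
#' potential, rate, verdict, bridge count and hotspot touches), plus the
#' distance-activity fit when supplied.  Serialisation is stable: the same
#' input always yields byte-identical JSON.
#'
#' @param calls list of `compatibility_call` objects.
#' @param fit optional `distance_activity_fit`.
#' @param bridges optional named list (by carrier id) of
#'   `salt_bridge_census` tables.
#' @param hotspot_reports optional named list (by carrier id) of
#'   `hotspot_report` objects.
#' @return A `screen_report` list with elements `carriers` (list, input
#'   order), and optionally `fit`.
#' @export
render_report <- function(calls, fit = NULL, bridges = NULL,
                          hotspot_reports = NULL) {
  entries <- lapply(calls, function(x) {
    id <- x$carrier_id
    b <- bridges[[id]]
    hr <- hotspot_reports[[id]]
    entry <- list(
      carrier_id = id,
      role_class = x$role_class,
      per_model_R = round(x$per_model_R, 3),
      mean_R = round(x$mean_R, 3),
      effective_potential_mV = x$effective_potential_mV,
      delta_g_eV = round(x$delta_g, 4),
      regime = x$regime,
      log10_rate_at_mean_R = round(x$log10_rate_at_mean_R, 3),
      distance_pass = x$distance_pass,
      rate_pass = x$rate_pass,
      verdict = x$verdict)
    if (!is.null(b)) entry$n_salt_bridges <- nrow(b)
    if (!is.null(hr))
      entry$hotspot_touches <- vapply(hr$contacts, function(d)
        if (is.null(d)) NA_integer_ else nrow(d), 0L)
    entry
  })
  out <- list(carriers = entries)
  if (!is.null(fit))
    out$fit <- list(n = fit$n, slope = round(fit$slope, 4),
                    intercept = round(fit$intercept, 4),
                    r_squared = round(fit$r_squared, 4))
  structure(out, class = "screen_report")
}

#' Serialise a screening report as JSON or a summary table
#'
#' @param report a `screen_report` from [render_report()].
#' @return `report_json()` returns a single JSON string (deterministic;
#'   serialising twice is byte-identical).  `report_table()` returns one
#'   summary row per carrier.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE))
}

#' @rdname report_json
#' @export
report_table <- function(report) {
  do.call(rbind, lapply(report$carriers, function(e) {
    data.frame(carrier_id = e$carrier_id, role_class = e$role_class,
               mean_R = e$mean_R,
               effective_potential_mV = e$effective_potential_mV,
               log10_rate = e$log10_rate_at_mean_R,
               n_salt_bridges = e$n_salt_bridges %||% NA_integer_,
               verdict = e$verdict, stringsAsFactors = FALSE)
  }))
}
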