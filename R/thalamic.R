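# Thalamocortical connectivity profiling. Connectivity is summed from each
# hemisphere's seven thalamic parcels to the ipsilateral cortical parcels
# of each lobe (contralateral thalamocortical edges are ignored), giving
# ten (hemisphere, lobe) sums per scan.

#' Thalamocortical connectivity per ipsilateral lobe
#'
#' For each hemisphere, sums the streamline weight between that
#' hemisphere's thalamic parcels and the same hemisphere's cortical
#' parcels of each lobe.
#'
#' @param x A `connectome` or adjacency matrix.
#' @param parcellation The matching `parcellation`.
#' @return Data frame with columns `hemisphere`, `lobe`, `streamline_sum`
#'   (10 rows, ordered left then right, lobes in taxonomy order).
#' @export
thalamocortical_connectivity <- function(x, parcellation) {
  w <- as_adjacency(x)
  if (nrow(w) != nrow(parcellation))
    stop("matrix dimension does not match parcellation", call. = FALSE)
  cort <- parcellation$structure_class == "cortical"
  if (any(is.na(parcellation$lobe[cort])))
    stop("cortical parcel without lobe assignment", call. = FALSE)
  lobes <- attr(parcellation, "lobes")
  out <- expand.grid(lobe = lobes, hemisphere = c("left", "right"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("hemisphere", "lobe")]
  out$streamline_sum <- mapply(function(h, l) {
    thal <- parcellation$structure_class == "thalamic" &
      parcellation$hemisphere == h
    ctx <- cort & parcellation$hemisphere == h & parcellation$lobe == l
    sum(w[thal, ctx, drop = FALSE])
  }, out$hemisphere, out$lobe)
  rownames(out) <- NULL
  out
}

lobe_key <- function(hemisphere, lobe) paste(hemisphere, lobe, sep = ":")

#' Per-lobe Z-score changes between paired scans
#'
#' Z-scores both scans' ten thalamocortical lobe sums against a normative
#' model fitted on control lobe sums, and returns the late-minus-early
#' change per (hemisphere, lobe).
#'
#' @param early,late Profiles from [thalamocortical_connectivity()] for the
#'   early and late scan of one patient.
#' @param model `normative_model` over the ten lobe-sum features (named
#'   `"<hemisphere>:<lobe>"`).
#' @param age_early,age_late Ages at each scan, years.
#' @param sex `"male"` or `"female"`.
#' @return Data frame `hemisphere`, `lobe`, `z_early`, `z_late`, `dz`.
#' @export
lobe_z_changes <- function(early, late, model, age_early, age_late, sex) {
  keys <- lobe_key(early$hemisphere, early$lobe)
  stopifnot(identical(keys, lobe_key(late$hemisphere, late$lobe)),
            identical(keys, model$features))
  ze <- zscore_features(model, early$streamline_sum, age_early, sex,
                        warn_extrapolation = FALSE)
  zl <- zscore_features(model, late$streamline_sum, age_late, sex,
                        warn_extrapolation = FALSE)
  data.frame(hemisphere = early$hemisphere, lobe = early$lobe,
             z_early = ze, z_late = zl, dz = zl - ze,
             stringsAsFactors = FALSE)
}

#' Within-patient z-of-z for the affected lobe
#'
#' Standardizes the ten per-lobe Z-score changes within the patient
#' (subtract their mean, divide by their SD) and returns the affected
#' lobe's standardized value. Asks whether the epilepsy-affected lobe's
#' thalamocortical change stands out from the patient's other lobes.
#'
#' @param delta_z Numeric vector of 10 per-lobe Z-score changes, named
#'   `"<hemisphere>:<lobe>"`.
#' @param affected_hemisphere,affected_lobe The affected lobe's key.
#' @return Scalar z-of-z; `NA` with a warning when the ten changes have
#'   zero spread.
#' @export
affected_lobe_z_of_z <- function(delta_z, affected_hemisphere, affected_lobe) {
  if (length(delta_z) != 10L)
    stop("expected 10 per-lobe changes, got ", length(delta_z), call. = FALSE)
  if (any(!is.finite(delta_z)))
    stop("non-finite lobe changes", call. = FALSE)
  key <- lobe_key(affected_hemisphere, affected_lobe)
  idx <- match(key, names(delta_z))
  if (is.na(idx)) stop("affected lobe ", key, " not in profile", call. = FALSE)
  s <- sd(delta_z)
  if (s == 0) {
    warning("zero spread across lobes: z-of-z undefined", call. = FALSE)
    return(NA_real_)
  }
  (delta_z[[idx]] - mean(delta_z)) / s
}

thalamic_parcel_ids <- function(parcellation) {
  parcellation$parcel_id[parcellation$structure_class == "thalamic"]
}
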