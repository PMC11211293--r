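#' Remove intrahepatic vessel blood from a label volume
#'
#' Produces the blood-free counterpart of a label volume: every hepatic- and
#' portal-vein voxel inside the liver is cleared, so liver/remnant/resect
#' masks derived from the result are blood-free. IVC voxels and the
#' extrahepatic part of the main portal vein are left untouched (they are
#' never counted in liver volumetry in either setting).
#'
#' @param volume A [label_volume] with parenchyma and vessel labels.
#' @return A [label_volume] with intrahepatic vessel voxels set to 0.
#' @export
blood_free_masks <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  if (!any(structure_mask(volume, "PARENCHYMA")))
    stop("volume has no liver (remnant/resect) voxels", call. = FALSE)
  inside <- intrahepatic_vessel_mask(volume)
  grid <- volume$grid
  grid[inside] <- 0L
  label_volume(grid, volume$spacing, volume$label_map)
}

#' Candidacy thresholds by liver condition
#'
#' Minimum FLR% required before major hepatectomy: 20% for healthy livers,
#' 30% for hepatic steatosis, 40% for cirrhosis.
#'
#' @return Named numeric vector of thresholds in percent.
#' @export
candidacy_thresholds <- function() c(healthy = 20, fatty = 30, cirrhosis = 40)

#' Blood-filled and blood-free liver volumetry
#'
#' Computes total liver volume (TLV), lesion volume, intrahepatic hepatic-
#' and portal-vein blood volumes, the future liver remnant (FLR) and FLR% in
#' both settings:
#' \deqn{FLR\% = 100 \cdot FLR / (TLV - V_{Lesion})}
#' evaluated with blood-filled and with blood-free FLR and TLV; the lesion
#' volume is the same in both settings. Vessel and lesion voxels are
#' assigned to the remnant or resect side by the resection plane.
#'
#' @param x A `patient_phantom` (uses its ground truth and plan) or a
#'   [label_volume].
#' @param plan A [resection_plan()] (required for a bare label volume).
#' @param ... Unused.
#' @return A one-row tibble: `tlv_filled_ml`, `tlv_free_ml`, `v_lesion_ml`,
#'   `v_hv_ml`, `v_pv_ml`, `flr_filled_ml`, `flr_free_ml`,
#'   `flr_pct_filled`, `flr_pct_free`.
#' @export
volumetry <- function(x, ...) UseMethod("volumetry")

#' @rdname volumetry
#' @export
volumetry.patient_phantom <- function(x, ...) {
  volumetry.label_volume(x$truth, plan = x$resection, ...)
}

#' @rdname volumetry
#' @export
volumetry.label_volume <- function(x, plan = NULL, ...) {
  if (is.null(plan))
    stop("a resection plan is required for volumetry", call. = FALSE)
  remnant <- structure_mask(x, "REMNANT")
  resect <- structure_mask(x, "RESECT")
  if (!any(remnant) && !any(resect))
    stop("volume has no remnant/resect partition", call. = FALSE)
  lesion <- structure_mask(x, "LESION")
  hv <- intrahepatic_vessel_mask(x, "hepatic")
  pv <- intrahepatic_vessel_mask(x, "portal")
  vessels <- hv | pv

  side <- plane_side_array(plan, dim(x$grid), x$spacing)
  remnant_side <- side <= 0

  n_rem <- sum(remnant)
  n_les <- sum(lesion)
  n_les_rem <- sum(lesion & remnant_side)
  n_hv <- sum(hv)
  n_pv <- sum(pv)
  n_ves_rem <- sum(vessels & remnant_side)

  n_tlv_filled <- n_rem + sum(resect) + n_les + n_hv + n_pv
  n_tlv_free <- n_tlv_filled - n_hv - n_pv
  n_flr_filled <- n_rem + n_les_rem + n_ves_rem
  n_flr_free <- n_flr_filled - n_ves_rem

  if (n_tlv_filled - n_les <= 0 || n_tlv_free - n_les <= 0)
    stop("degenerate nontumor liver volume (TLV - V_lesion <= 0)",
         call. = FALSE)

  vv <- prod(x$spacing) / 1000
  tibble(
    tlv_filled_ml = n_tlv_filled * vv,
    tlv_free_ml = n_tlv_free * vv,
    v_lesion_ml = n_les * vv,
    v_hv_ml = n_hv * vv,
    v_pv_ml = n_pv * vv,
    flr_filled_ml = n_flr_filled * vv,
    flr_free_ml = n_flr_free * vv,
    flr_pct_filled = 100 * n_flr_filled / (n_tlv_filled - n_les),
    flr_pct_free = 100 * n_flr_free / (n_tlv_free - n_les)
  )
}

#' Resection-candidacy decision from FLR%
#'
#' A patient is a candidate for major hepatectomy when FLR% is strictly
#' larger than the threshold for their liver condition (20/30/40% for
#' healthy/fatty/cirrhotic livers).
#'
#' @param flr_pct FLR percentage(s) in `[0, 100]`.
#' @param condition Liver condition(s): `healthy`, `fatty` or `cirrhosis`.
#' @param basis Which setting the FLR% came from (`blood_filled` or
#'   `blood_free`); carried through for reporting.
#' @return A tibble: `candidate`, `threshold_pct`, `condition`, `basis`,
#'   `flr_pct`.
#' @export
#' @examples
#' candidacy(35, "healthy")
#' candidacy(35, "cirrhosis")
candidacy <- function(flr_pct, condition,
                      basis = c("blood_free", "blood_filled")) {
  basis <- match.arg(basis)
  thr <- candidacy_thresholds()
  if (!all(condition %in% names(thr)))
    stop("unknown liver condition: ",
         paste(setdiff(condition, names(thr)), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(flr_pct)) || any(flr_pct < 0) || any(flr_pct > 100))
    stop("flr_pct must lie in [0, 100]", call. = FALSE)
  t <- unname(thr[condition])
  tibble(candidate = flr_pct > t, threshold_pct = t,
         condition = condition, basis = basis, flr_pct = flr_pct)
}
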