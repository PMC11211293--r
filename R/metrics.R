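#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |P ∩ G| / (|P| + |G|)`, the voxel-overlap agreement between a
#' prediction mask `P` and a ground-truth mask `G`. Two empty masks score 1
#' (perfect agreement on absence).
#'
#' @param pred,truth Logical (or 0/1) arrays of identical shape.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
#' dice(a, a)
dice <- function(pred, truth) {
  check_same_shape(pred, truth)
  np <- sum(pred != 0)
  ng <- sum(truth != 0)
  if (np + ng == 0) return(1)
  2 * sum(pred != 0 & truth != 0) / (np + ng)
}

#' Volumetric similarity of two binary masks
#'
#' `VS = 1 - |V_G - V_P| / (V_G + V_P)`: agreement of the two volumes
#' irrespective of where they sit, so `VS >= DSC` always. Two empty masks
#' score 1; exactly one empty mask scores 0.
#'
#' @inheritParams dice
#' @return A value in `[0, 1]`.
#' @export
volumetric_similarity <- function(pred, truth) {
  check_same_shape(pred, truth)
  vp <- sum(pred != 0)
  vg <- sum(truth != 0)
  if (vp + vg == 0) return(1)
  1 - abs(vg - vp) / (vg + vp)
}

check_same_shape <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("masks must share the same shape", call. = FALSE)
  invisible(TRUE)
}

#' Physical volume of a mask in millilitres
#'
#' @param mask Logical (or 0/1) array.
#' @param spacing Voxel spacing in mm (length 3).
#' @return Volume in mL (`voxels * sx * sy * sz / 1000`).
#' @export
mask_volume_ml <- function(mask, spacing) {
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(mask != 0) * prod(spacing) / 1000
}

#' Segmentation-quality metrics per structure group
#'
#' Computes DSC, VS and the physical volumes of prediction and truth for
#' each structure group. Following how segmentation studies report one
#' figure per vessel system, the default groups are the liver
#' (parenchyma + lesion), the union of the five hepatic veins, and the
#' union of the three portal veins.
#'
#' @param pred,truth [label_volume] objects on the same grid.
#' @param groups Character vector of group names understood by
#'   [structure_mask()] (plus `"LIVER"` as an alias for parenchyma+lesion).
#' @return A tibble with one row per group: `structure_group`, `dsc`, `vs`,
#'   `volume_pred_ml`, `volume_truth_ml`.
#' @export
overlap_metrics <- function(pred, truth,
                            groups = c("LIVER", "HEPATIC_VEINS",
                                       "PORTAL_VEINS")) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  check_same_shape(pred$grid, truth$grid)
  rows <- lapply(groups, function(g) {
    sel <- if (identical(g, "LIVER")) c("PARENCHYMA", "LESION") else g
    pm <- structure_mask(pred, sel)
    tm <- structure_mask(truth, sel)
    tibble(
      structure_group = g,
      dsc = dice(pm, tm),
      vs = volumetric_similarity(pm, tm),
      volume_pred_ml = mask_volume_ml(pm, pred$spacing),
      volume_truth_ml = mask_volume_ml(tm, truth$spacing)
    )
  })
  dplyr::bind_rows(rows)
}
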