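#' Structure vocabulary and integer label codes
#'
#' The package works on a closed vocabulary of liver structures: the
#' remnant/resect parenchyma partition, the lesion, five hepatic veins
#' (RHV, MHV, LHV, SRHV, IRHV), three portal veins (MPV, RPV, LPV) and the
#' inferior vena cava (IVC), which serves only as an extrahepatic landmark.
#'
#' @return A named integer vector mapping structure name to label code.
#' @export
#' @examples
#' structure_codes()
structure_codes <- function() {
  c(REMNANT = 1L, RESECT = 2L, LESION = 3L,
    RHV = 4L, MHV = 5L, LHV = 6L, SRHV = 7L, IRHV = 8L,
    MPV = 9L, RPV = 10L, LPV = 11L, IVC = 12L)
}

#' @rdname structure_codes
#' @export
hepatic_vein_names <- function() c("RHV", "MHV", "LHV", "SRHV", "IRHV")

#' @rdname structure_codes
#' @export
portal_vein_names <- function() c("MPV", "RPV", "LPV")

#' Labeled 3D volume with physical voxel spacing
#'
#' The universal image currency of the package: a 3D array of nonnegative
#' integer labels together with the physical voxel spacing in millimetres
#' and a `label_map` naming each code. The physical coordinate of voxel
#' `(i, j, k)` (1-based R indices) is `(i - 1, j - 1, k - 1) * spacing` mm.
#'
#' @param grid 3D array of nonnegative integers; every nonzero value must
#'   appear in `label_map`.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param label_map Named integer vector mapping structure names to codes.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1),
                         label_map = structure_codes()) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (any(spacing <= 0) || length(spacing) != 3L)
    stop("`spacing` must be three positive lengths (mm)", call. = FALSE)
  storage.mode(grid) <- "integer"
  if (any(grid < 0L, na.rm = TRUE))
    stop("`grid` labels must be nonnegative integers", call. = FALSE)
  present <- setdiff(unique(as.integer(grid)), 0L)
  unknown <- setdiff(present, as.integer(label_map))
  if (length(unknown) > 0)
    stop("grid contains labels absent from label_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  present <- names(x$label_map)[x$label_map %in% unique(as.integer(x$grid))]
  cat("  structures present:", paste(present, collapse = ", "), "\n")
  invisible(x)
}

#' Extract a binary mask for one or more structures
#'
#' Besides the literal structure names, three group names are understood:
#' `"PARENCHYMA"` (REMNANT + RESECT), `"HEPATIC_VEINS"` and `"PORTAL_VEINS"`.
#'
#' @param volume A [label_volume].
#' @param structures Character vector of structure or group names.
#' @return Logical 3D array.
#' @export
structure_mask <- function(volume, structures) {
  stopifnot(inherits(volume, "label_volume"))
  expand <- function(s) {
    switch(s,
           PARENCHYMA = c("REMNANT", "RESECT"),
           HEPATIC_VEINS = hepatic_vein_names(),
           PORTAL_VEINS = portal_vein_names(),
           s)
  }
  names_all <- unique(unlist(lapply(structures, expand)))
  missing <- setdiff(names_all, names(volume$label_map))
  if (length(missing) > 0)
    stop("unknown structure(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  codes <- volume$label_map[names_all]
  array(volume$grid %in% as.integer(codes), dim(volume$grid))
}

# Count, for every voxel, how many of its 6 axis-parallel rays hit `ref`.
# Used to decide whether a vessel voxel is enclosed by liver parenchyma.
ray_hit_count <- function(ref) {
  d <- dim(ref)
  total <- array(0L, d)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    pr <- aperm(ref, perm)
    n <- dim(pr)[1]
    m <- matrix(pr, nrow = n)
    before <- matrix(FALSE, nrow = n, ncol = ncol(m))
    run <- rep(FALSE, ncol(m))
    for (i in seq_len(n)) {
      before[i, ] <- run
      run <- run | m[i, ]
    }
    after <- matrix(FALSE, nrow = n, ncol = ncol(m))
    run <- rep(FALSE, ncol(m))
    for (i in rev(seq_len(n))) {
      after[i, ] <- run
      run <- run | m[i, ]
    }
    cnt <- array(as.integer(before) + as.integer(after), dim = dim(pr))
    total <- total + aperm(cnt, order(perm))
  }
  total
}

#' Intrahepatic vessel voxels
#'
#' Hepatic veins and the right/left portal veins are intrahepatic by
#' construction; the main portal vein may extend outside the liver, so its
#' voxels are classified by a 6-ray enclosure test against the
#' parenchyma/lesion solid (a voxel counts as intrahepatic when at least 4 of
#' its 6 axis-parallel rays hit parenchyma or lesion). The IVC is never
#' intrahepatic.
#'
#' @param volume A [label_volume].
#' @param vessels One of `"all"`, `"hepatic"`, `"portal"`.
#' @return Logical 3D array of intrahepatic vessel voxels.
#' @export
intrahepatic_vessel_mask <- function(volume,
                                     vessels = c("all", "hepatic", "portal")) {
  vessels <- match.arg(vessels)
  hv <- structure_mask(volume, "HEPATIC_VEINS")
  if (vessels == "hepatic") return(hv)
  pv <- structure_mask(volume, c("RPV", "LPV"))
  mpv <- structure_mask(volume, "MPV")
  if (any(mpv)) {
    ref <- structure_mask(volume, c("PARENCHYMA", "LESION"))
    enclosed <- ray_hit_count(ref) >= 4L
    mpv <- mpv & enclosed
  }
  pv <- pv | mpv
  if (vessels == "portal") pv else (hv | pv)
}

#' Liver mask in the blood-filled or blood-free setting
#'
#' Blood-filled: parenchyma + lesion + intrahepatic vessel voxels (what CT
#' volumetry measures). Blood-free: parenchyma + lesion only (what an
#' exsanguinated graft weighs).
#'
#' @param volume A [label_volume].
#' @param setting `"blood_filled"` or `"blood_free"`.
#' @return Logical 3D array.
#' @export
liver_mask <- function(volume, setting = c("blood_filled", "blood_free")) {
  setting <- match.arg(setting)
  base <- structure_mask(volume, c("PARENCHYMA", "LESION"))
  if (setting == "blood_free") return(base)
  base | intrahepatic_vessel_mask(volume)
}

# Physical coordinates (mm) of a set of voxels given by linear index.
voxel_coords_mm <- function(lin, dim, spacing) {
  lin <- lin - 1L
  i <- lin %% dim[1]
  j <- (lin %/% dim[1]) %% dim[2]
  k <- lin %/% (dim[1] * dim[2])
  cbind(i * spacing[1], j * spacing[2], k * spacing[3])
}

# Euclidean distance (mm) from every voxel to the nearest TRUE voxel
# (Inf when the mask is empty).
distance_to_mask <- function(mask, spacing) {
  storage.mode(mask) <- "logical"
  d2 <- .edt_sq_cpp(mask, dim(mask), as.numeric(spacing))
  d2[d2 > 1e18] <- Inf
  sqrt(d2)
}

# Signed distance: positive inside `mask`, negative outside (mm).
signed_distance <- function(mask, spacing) {
  distance_to_mask(!mask, spacing) - distance_to_mask(mask, spacing)
}
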