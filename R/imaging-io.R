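#' Read a parametric image from NIfTI-1
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param subject_id,side,kind metadata attached to the returned object.
#' @return a \linkS4class{ParametricImage}.
#' @export
readParametricImage <- function(path, subject_id = NA_character_,
                                side = NA_character_, kind = "BR") {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stopf("malformed NIfTI file %s: %s", path,
                          conditionMessage(e), class = "pclasso_format_error"))
  vals <- array(as.numeric(img), dim = dim(img))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  methods::new("ParametricImage", values = vals, affine = aff,
               voxel_size = as.numeric(RNifti::pixdim(img))[1:3],
               subject_id = subject_id, side = side, kind = kind)
}

#' Write a parametric image to NIfTI-1
#'
#' Voxel values, voxel size and the affine (sform and qform) are preserved
#' through a write/read roundtrip.
#'
#' @param image a \linkS4class{ParametricImage}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeParametricImage <- function(image, path) {
  stopifnot(methods::is(image, "ParametricImage"))
  nim <- RNifti::asNifti(image@values)
  RNifti::pixdim(nim) <- image@voxel_size
  aff <- structure(image@affine, code = 2L)
  RNifti::`sform<-`(nim, aff) -> nim
  RNifti::`qform<-`(nim, aff) -> nim
  ok <- tryCatch({RNifti::writeNifti(nim, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stopf("cannot write image to %s", path, class = "pclasso_io_error")
  invisible(path)
}

#' Write / read a labeled template as an integer NIfTI-1 label map
#'
#' @param template a \linkS4class{LabeledTemplate}.
#' @param path NIfTI-1 path.
#' @return \code{writeTemplate}: the path invisibly; \code{readTemplate}: a
#'   \linkS4class{LabeledTemplate}.
#' @export
writeTemplate <- function(template, path) {
  stopifnot(methods::is(template, "LabeledTemplate"))
  nim <- RNifti::asNifti(array(as.numeric(template@labels),
                               dim = dim(template@labels)))
  RNifti::pixdim(nim) <- template@voxel_size
  RNifti::writeNifti(nim, path, datatype = "int16")
  invisible(path)
}

#' @rdname writeTemplate
#' @export
readTemplate <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stopf("malformed NIfTI file %s: %s", path,
                          conditionMessage(e), class = "pclasso_format_error"))
  methods::new("LabeledTemplate",
               labels = array(as.integer(img), dim = dim(img)),
               voxel_size = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Compute a binding-ratio image
#'
#' Divides every voxel of a static activity image by the mean activity over
#' a nonspecific reference region, yielding a dimensionless binding-ratio
#' (BR) image. The reference mean and voxel count are recorded in the
#' result's \code{meta}.
#'
#' @param activity_image \linkS4class{ParametricImage} of raw activity.
#' @param reference_mask logical/0-1 array (or ParametricImage) of the same
#'   grid marking the reference region.
#' @return a BR \linkS4class{ParametricImage}.
#' @export
computeBR <- function(activity_image, reference_mask) {
  stopifnot(methods::is(activity_image, "ParametricImage"))
  mask <- if (methods::is(reference_mask, "ParametricImage"))
    reference_mask@values else reference_mask
  if (!identical(dim(mask), dim(activity_image@values)))
    stopf("reference mask grid does not match the activity image")
  sel <- mask > 0
  if (!any(sel))
    stopf("reference mask is empty", class = "pclasso_validation_error")
  ref_mean <- mean(activity_image@values[sel])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stopf("mean reference activity must be positive (got %g)", ref_mean,
          class = "pclasso_computation_error")
  out <- activity_image
  out@values <- activity_image@values / ref_mean
  out@kind <- "BR"
  out@meta <- c(activity_image@meta,
                list(reference_mean = ref_mean, reference_voxels = sum(sel)))
  methods::validObject(out)
  out
}

#' Ordered ROI voxel index of a template
#'
#' Returns the 0-based (i, j, k) coordinates of all voxels carrying
#' \code{roi_label}, in lexicographic order over (i, j, k). This fixed order
#' defines the column order of every \linkS4class{VoxelMatrix}.
#'
#' @param template a \linkS4class{LabeledTemplate}.
#' @param roi_label integer label (1 = putamen, 2 = caudate+VS).
#' @return integer V x 3 matrix.
#' @export
roiVoxelIndex <- function(template, roi_label) {
  if (!any(template@labels == roi_label))
    stopf("label %s not present in template", roi_label,
          class = "pclasso_validation_error")
  idx <- which(template@labels == roi_label, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  idx <- idx - 1L
  dimnames(idx) <- list(NULL, c("i", "j", "k"))
  idx
}

#' Assemble a subject-by-voxel matrix over one ROI
#'
#' Row n holds subject n's BR values at the template's ROI voxels, columns
#' in the fixed lexicographic voxel order of \code{\link{roiVoxelIndex}}.
#'
#' @param images list of \linkS4class{ParametricImage}s sharing the template
#'   grid (and typically a side).
#' @param template the \linkS4class{LabeledTemplate}.
#' @param roi_label integer ROI label.
#' @return a \linkS4class{VoxelMatrix}.
#' @export
extractVoxelMatrix <- function(images, template, roi_label) {
  if (length(images) < 1) stopf("at least one image required")
  gdim <- dim(template@labels)
  for (im in images)
    if (!identical(dim(im@values), gdim))
      stopf("image grid %s does not match template grid %s",
            paste(dim(im@values), collapse = "x"),
            paste(gdim, collapse = "x"), class = "pclasso_shape_error")
  vidx <- roiVoxelIndex(template, roi_label)
  lin <- 1L + vidx[, 1] + gdim[1] * (vidx[, 2] + gdim[2] * vidx[, 3])
  dat <- t(vapply(images, function(im) im@values[lin],
                  numeric(nrow(vidx))))
  sides <- unique(vapply(images, function(im) im@side, character(1)))
  methods::new("VoxelMatrix", data = dat, voxel_index = vidx,
               roi_label = as.integer(roi_label),
               side = if (length(sides) == 1) sides else "mixed",
               subject_ids = vapply(images, function(im) im@subject_id,
                                    character(1)))
}

#' Sort left/right hemisphere images into better/worse
#'
#' The brain hemisphere contralateral to the worse (more clinically
#' affected) body side is labeled "worse"; the other hemisphere "better".
#'
#' @param left_image,right_image \linkS4class{ParametricImage}s of the two
#'   hemispheres of one subject.
#' @param worse_body_side "left" or "right" (from
#'   \code{\link{assignSides}}).
#' @return list(better = , worse = ) of relabeled images.
#' @export
sortSides <- function(left_image, right_image, worse_body_side) {
  if (is.na(worse_body_side) ||
      !worse_body_side %in% c("left", "right"))
    stopf("worse_body_side must be 'left' or 'right'",
          class = "pclasso_validation_error")
  relabel <- function(im, side) { im@side <- side; im }
  if (worse_body_side == "left")
    list(better = relabel(left_image, "better"),
         worse = relabel(right_image, "worse"))
  else
    list(better = relabel(right_image, "better"),
         worse = relabel(left_image, "worse"))
}
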