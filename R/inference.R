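#' Translate a CBCT volume to synthetic CT, slice by slice
#'
#' Each axial slice is channel-encoded, mapped through the generator, and
#' decoded back to HU via the affine channel-sum decoder; the body mask is
#' re-applied with an air fill, so non-anatomy stays at -1024 HU. The output
#' grid is identical to the input grid.
#'
#' @param vol a clipped, masked [ct_volume].
#' @param gen a trained generator `cut_network`.
#' @param mask the [body_mask] of `vol`.
#' @param part the [partition_edges()] partition used in training.
#' @return A [ct_volume] of synthetic-CT HU values.
#' @export
translate_volume <- function(vol, gen, mask, part = partition_edges()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(gen, "cut_network"),
            inherits(mask, "body_mask"))
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop("volume and mask grids disagree", call. = FALSE)
  out <- vol$voxels
  for (k in seq_len(dim(vol$voxels)[3])) {
    xin <- channels_to_net(encode_slice(vol$voxels[, , k], part)$channels)
    ynet <- net_apply(gen, xin)
    out[, , k] <- decode_slice(net_to_channels(ynet), part)
  }
  res <- vol
  res$voxels <- out
  apply_mask(clip_hu(res), mask, fill = -1024)
}
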