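#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData rowData
NULL

#' LfqExperiment: a protein-by-sample LFQ intensity container
#'
#' Extends \linkS4class{SummarizedExperiment} with a single \code{"lfq"}
#' assay and a scale flag. Columns are samples; \code{colData} must carry a
#' \code{group} factor (\code{"control"}/\code{"case"}) and, before technical
#' replicates are averaged, a \code{biosample} column mapping each run to its
#' biological sample. Missing intensities are \code{NA}; on the linear scale
#' all values are non-negative.
#'
#' @slot scaleFlag either \code{"linear"} or \code{"log2"}.
#' @export
setClass("LfqExperiment",
  contains = "SummarizedExperiment",
  slots = c(scaleFlag = "character"),
  prototype = prototype(scaleFlag = "log2")
)

setValidity("LfqExperiment", function(object) {
  msg <- NULL
  if (!object@scaleFlag %in% c("linear", "log2"))
    msg <- c(msg, "scaleFlag must be 'linear' or 'log2'")
  if (!"lfq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'lfq' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (!all(cd$group %in% c("control", "case")))
    msg <- c(msg, "groups must be 'control' or 'case'")
  if (object@scaleFlag == "linear") {
    a <- SummarizedExperiment::assay(object, "lfq")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "negative linear intensities are not allowed")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an LfqExperiment
#'
#' @param intensities numeric matrix, proteins in rows, samples in columns;
#'   missing values as \code{NA}.
#' @param group character/factor per sample, \code{"control"} or \code{"case"}.
#' @param biosample optional character per sample naming the biological sample
#'   each technical replicate belongs to; defaults to one biosample per column.
#' @param scale \code{"log2"} (default) or \code{"linear"}.
#' @param rowData optional per-protein annotation (data.frame).
#' @return an \linkS4class{LfqExperiment}.
#' @examples
#' m <- matrix(rnorm(20, 25), 5, 4,
#'   dimnames = list(paste0("P", 1:5), paste0("S", 1:4)))
#' lfq <- LfqExperiment(m, group = rep(c("control", "case"), each = 2))
#' @export
LfqExperiment <- function(intensities, group, biosample = colnames(intensities),
                          scale = c("log2", "linear"), rowData = NULL) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("S", seq_len(ncol(intensities)))
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("P", seq_len(nrow(intensities)))
  if (length(group) != ncol(intensities))
    stop("'group' must have one entry per sample column")
  if (is.null(biosample)) biosample <- colnames(intensities)
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             biosample = as.character(biosample),
                             row.names = colnames(intensities))
  se <- SummarizedExperiment(assays = list(lfq = intensities), colData = cd)
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  new("LfqExperiment", se, scaleFlag = scale)
}

#' @describeIn LfqExperiment intensity scale of the stored assay.
#' @param x an LfqExperiment.
#' @export
scaleFlag <- function(x) x@scaleFlag

#' @describeIn LfqExperiment the LFQ intensity matrix.
#' @export
lfqAssay <- function(x) SummarizedExperiment::assay(x, "lfq")

#' @describeIn LfqExperiment per-sample group labels.
#' @export
sampleGroups <- function(x) SummarizedExperiment::colData(x)$group

#' Convert an LfqExperiment between linear and log2 scale
#'
#' Zero linear intensities are treated as missing (MaxQuant convention).
#'
#' @param x an LfqExperiment.
#' @param scale target scale.
#' @return an LfqExperiment on the requested scale.
#' @export
setLfqScale <- function(x, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (scaleFlag(x) == scale) return(x)
  a <- lfqAssay(x)
  if (scale == "log2") {
    a[!is.na(a) & a == 0] <- NA
    a <- log2(a)
  } else {
    a <- 2^a
  }
  SummarizedExperiment::assay(x, "lfq") <- a
  x@scaleFlag <- scale
  validObject(x)
  x
}

setMethod("show", "LfqExperiment", function(object) {
  a <- lfqAssay(object)
  cat("LfqExperiment:", nrow(a), "proteins x", ncol(a), "samples [",
      object@scaleFlag, "scale ]\n")
  tab <- table(sampleGroups(object))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(a)),
      sprintf("(%.1f%%)\n", 100 * mean(is.na(a))))
})

#' BiosensorStack: multi-channel image volume with an ROI label mask
#'
#' Holds a channel-major 4-d intensity array (channel, z, y, x) and an
#' integer label mask of matching spatial shape (0 = background, k > 0 =
#' axon/ROI id).
#'
#' @slot img numeric array, dim = c(n_channels, z, y, x).
#' @slot mask integer array, dim = c(z, y, x).
#' @slot channelNames character, one per channel.
#' @slot voxelSize numeric length-3 voxel size in micrometres (z, y, x) or
#'   \code{NA} when unknown.
#' @export
setClass("BiosensorStack",
  slots = c(img = "array", mask = "array",
            channelNames = "character", voxelSize = "numeric")
)

setValidity("BiosensorStack", function(object) {
  msg <- NULL
  if (length(dim(object@img)) != 4)
    msg <- c(msg, "img must be a 4-d array (channel, z, y, x)")
  else {
    if (dim(object@img)[1] < 2)
      msg <- c(msg, "at least two channels are required")
    if (!identical(dim(object@mask), dim(object@img)[-1]))
      msg <- c(msg, "mask shape must equal the spatial shape of img")
    if (length(object@channelNames) != dim(object@img)[1])
      msg <- c(msg, "one channel name per channel required")
  }
  if (any(object@img < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BiosensorStack
#' @param img 4-d array (channel, z, y, x), non-negative.
#' @param mask integer array (z, y, x); 0 is background.
#' @param channelNames channel names; default \code{"ch1"}, \code{"ch2"}, ...
#' @param voxelSize voxel edge lengths in µm (z, y, x); \code{NA} if unknown.
#' @return a \linkS4class{BiosensorStack}.
#' @export
BiosensorStack <- function(img, mask,
                           channelNames = paste0("ch", seq_len(dim(img)[1])),
                           voxelSize = rep(NA_real_, 3)) {
  storage.mode(mask) <- "integer"
  new("BiosensorStack", img = img, mask = mask,
      channelNames = channelNames, voxelSize = voxelSize)
}

setMethod("show", "BiosensorStack", function(object) {
  d <- dim(object@img)
  cat("BiosensorStack:", d[1], "channels (",
      paste(object@channelNames, collapse = ", "), "), volume",
      paste(d[-1], collapse = " x "), "\n")
  ids <- setdiff(unique(as.vector(object@mask)), 0L)
  cat("  ROIs:", length(ids), " background voxels:",
      sum(object@mask == 0L), "\n")
})

#' @describeIn BiosensorStack axon/ROI ids present in the mask.
#' @param x a BiosensorStack.
#' @export
roiIds <- function(x) sort(setdiff(unique(as.vector(x@mask)), 0L))
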