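#' Read a MaxQuant-style proteinGroups table
#'
#' Consumes the tab-separated proteinGroups dialect: protein ids from
#' \code{"Majority protein IDs"} (first id of each group kept) and one
#' \code{"LFQ intensity <sample>"} column per sample. Rows flagged \code{+}
#' in \code{"Reverse"} or \code{"Potential contaminant"} (or
#' \code{"Contaminant"}) are dropped when those columns are present. Zero
#' intensities are treated as missing (MaxQuant convention), and the matrix
#' is returned on the log2 scale.
#'
#' @param path TSV file path.
#' @param group named character: sample name -> \code{"control"}/\code{"case"};
#'   defaults to \code{"control"} for every sample with a warning.
#' @param biosample optional named character: sample name -> biological
#'   sample (for technical replicates).
#' @return an \linkS4class{LfqExperiment} (log2 scale).
#' @export
readProteinGroups <- function(path, group = NULL, biosample = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- intersect(c("Majority protein IDs", "Protein IDs", "protein_id"),
                     colnames(tab))
  if (!length(idcol)) stop("no protein id column found in ", path)
  for (flag in c("Reverse", "Potential contaminant", "Contaminant")) {
    if (flag %in% colnames(tab)) tab <- tab[tab[[flag]] != "+", , drop = FALSE]
  }
  ids <- vapply(strsplit(as.character(tab[[idcol[1]]]), ";"),
                `[`, character(1), 1)
  lfq_cols <- grep("^LFQ intensity ", colnames(tab), value = TRUE)
  if (!length(lfq_cols)) stop("no 'LFQ intensity <sample>' columns in ", path)
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  m <- as.matrix(tab[, lfq_cols, drop = FALSE])
  dimnames(m) <- list(ids, samples)
  m[is.na(m) | m == 0] <- NA
  if (is.null(group)) {
    warning("no group mapping supplied; all samples set to 'control'")
    group <- setNames(rep("control", length(samples)), samples)
  }
  bs <- if (is.null(biosample)) samples else unname(biosample[samples])
  LfqExperiment(log2(m), group = unname(group[samples]), biosample = bs,
                scale = "log2")
}

#' Write an LfqExperiment in the proteinGroups dialect
#'
#' One \code{"Majority protein IDs"} column plus \code{"LFQ intensity
#' <sample>"} columns, tab-separated, on the linear scale. Missing values
#' are written per \code{missing_as}: empty cells or zeros.
#'
#' @param x an \linkS4class{LfqExperiment}.
#' @param path output TSV path.
#' @param missing_as \code{"empty"} or \code{"zero"}.
#' @export
writeLfqTsv <- function(x, path, missing_as = c("empty", "zero")) {
  missing_as <- match.arg(missing_as)
  lin <- setLfqScale(x, "linear")
  a <- lfqAssay(lin)
  df <- data.frame(`Majority protein IDs` = rownames(a), a,
                   check.names = FALSE)
  colnames(df)[-1] <- paste("LFQ intensity", colnames(a))
  if (missing_as == "zero") df[is.na(df)] <- 0
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the sample design of an LfqExperiment as TSV
#' @param x an \linkS4class{LfqExperiment}.
#' @param path output path.
#' @export
writeDesignTsv <- function(x, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  utils::write.table(data.frame(sample = rownames(cd), cd), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read an enzyme-abundance profile as TSV
#'
#' Two columns: enzyme, factor.
#' @param profile named numeric profile.
#' @param path file path.
#' @export
writeProfileTsv <- function(profile, path) {
  utils::write.table(data.frame(enzyme = names(profile),
                                factor = as.numeric(profile)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTsv
#' @export
readProfileTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(setNames(tab$factor, tab$enzyme),
            class = "EnzymeAbundanceProfile")
}

#' Write a BiosensorStack as multi-page TIFF
#'
#' Channel-major pages (channel 1 planes, then channel 2, ...), plus the
#' label mask as a separate single/multi-page TIFF. Intensities are scaled
#' to the 16-bit range on write and restored on read via a stored scale
#' factor in the mask path's sidecar; for round-trip fidelity within
#' quantisation only.
#'
#' @param stack a \linkS4class{BiosensorStack}.
#' @param img_path,mask_path output TIFF paths.
#' @export
writeStackTiff <- function(stack, img_path, mask_path) {
  d <- dim(stack@img)
  pages <- list()
  k <- 1
  scale <- max(stack@img, 1)
  for (c in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- stack@img[c, z, , ] / scale
    k <- k + 1
  }
  tiff::writeTIFF(pages, img_path, bits.per.sample = 16)
  mpages <- lapply(seq_len(d[2]), function(z) stack@mask[z, , ] / 65535)
  tiff::writeTIFF(mpages, mask_path, bits.per.sample = 16)
  writeLines(as.character(scale), paste0(img_path, ".scale"))
  invisible(img_path)
}

#' Read a BiosensorStack written by writeStackTiff
#' @param img_path,mask_path TIFF paths.
#' @param n_channels channel count of the stored stack.
#' @return a \linkS4class{BiosensorStack}.
#' @export
readStackTiff <- function(img_path, mask_path, n_channels = 2) {
  pages <- tiff::readTIFF(img_path, all = TRUE)
  scale <- as.numeric(readLines(paste0(img_path, ".scale")))
  nz <- length(pages) / n_channels
  dy <- dim(pages[[1]])
  img <- array(0, c(n_channels, nz, dy[1], dy[2]))
  k <- 1
  for (c in seq_len(n_channels)) for (z in seq_len(nz)) {
    img[c, z, , ] <- pages[[k]] * scale
    k <- k + 1
  }
  mpages <- tiff::readTIFF(mask_path, all = TRUE)
  mask <- array(0L, c(nz, dy[1], dy[2]))
  for (z in seq_len(nz)) mask[z, , ] <- as.integer(round(mpages[[z]] * 65535))
  BiosensorStack(img, mask)
}
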