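#' Read an ancestry hard-call table
#'
#' Reads the tab-separated ancestry-call format: a header line, columns
#' `chrom`, `pos`, then one dosage column per individual with values 0, 1,
#' 2 (copies of parent-1 ancestry) or `NA`. Rows are markers. Which
#' species is "parent 1" is a property of the upstream ancestry calls and
#' should be recorded alongside the file.
#'
#' @param path Path to the TSV file.
#' @return An [ancestry_matrix].
#' @export
read_ancestry_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || !all(c("chrom", "pos") %in% names(tab)))
    stop("expected columns 'chrom', 'pos' and at least one individual")
  ind <- setdiff(names(tab), c("chrom", "pos", "cM"))
  dos <- as.matrix(tab[, ind, drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "integer")
  bad <- which(!(dos %in% c(0L, 1L, 2L, NA)) |
                 (is.na(dos) & !is.na(as.matrix(tab[, ind, drop = FALSE]))))
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("malformed dosage at marker row %d, individual '%s'",
                 (i - 1) %% nrow(dos) + 1,
                 ind[(i - 1) %/% nrow(dos) + 1]))
  }
  ancestry_matrix(dos, tab$chrom, tab$pos,
                  cM = if ("cM" %in% names(tab)) tab$cM else NULL)
}

#' Write an ancestry hard-call table
#'
#' @param x An [ancestry_matrix] or [sample_ancestry()] result.
#' @param path Output TSV path.
#' @param ids Optional individual identifiers (default `ind1`, `ind2`, ...).
#' @export
write_ancestry_table <- function(x, path, ids = NULL) {
  inp <- .scan_input(x)
  n <- ncol(inp$dosage)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(n))
  tab <- data.frame(chrom = inp$markers$chrom, pos = inp$markers$pos,
                    stringsAsFactors = FALSE)
  if (!is.null(inp$markers$cM)) tab$cM <- inp$markers$cM
  dos <- inp$dosage
  colnames(dos) <- ids
  utils::write.table(cbind(tab, dos), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write phased ancestry haplotypes
#'
#' TSV with columns `chrom`, `pos`, then two 0/1 columns per individual
#' (`<id>.1`, `<id>.2`), one per chromosome copy.
#'
#' @param x A [sample_ancestry()] result.
#' @param path Output TSV path.
#' @param ids Optional individual identifiers.
#' @export
write_phased_table <- function(x, path, ids = NULL) {
  if (!inherits(x, "ancestry_sample"))
    stop("phased output requires an ancestry_sample")
  n <- ncol(x$h1)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(n))
  H <- matrix(0L, nrow(x$h1), 2 * n)
  H[, seq(1, 2 * n, 2)] <- x$h1
  H[, seq(2, 2 * n, 2)] <- x$h2
  colnames(H) <- paste(rep(ids, each = 2), 1:2, sep = ".")
  tab <- data.frame(chrom = x$markers$chrom, pos = x$markers$bp,
                    cM = x$markers$cM, stringsAsFactors = FALSE)
  utils::write.table(cbind(tab, H), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read phased ancestry haplotypes
#'
#' Inverse of [write_phased_table()]; returns an object usable by
#' [pairwise_scan()] in phased mode.
#'
#' @param path Path to the TSV file.
#' @return An object of class `"ancestry_sample"` (generation unknown,
#'   recorded as `NA`).
#' @export
read_phased_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("chrom", "pos", "cM"), names(tab))
  hcols <- setdiff(names(tab), meta)
  if (length(hcols) < 2 || length(hcols) %% 2 != 0)
    stop("expected two haplotype columns per individual")
  H <- as.matrix(tab[, hcols, drop = FALSE])
  storage.mode(H) <- "integer"
  if (any(!(H %in% c(0L, 1L)))) stop("haplotype entries must be 0 or 1")
  h1 <- H[, seq(1, ncol(H), 2), drop = FALSE]
  h2 <- H[, seq(2, ncol(H), 2), drop = FALSE]
  markers <- data.frame(chrom = as.character(tab$chrom),
                        bp = as.numeric(tab$pos),
                        cM = if ("cM" %in% meta) as.numeric(tab$cM)
                             else NA_real_)
  frac <- colMeans(h1 + h2) / 2
  structure(list(h1 = h1, h2 = h2, dosage = h1 + h2, markers = markers,
                 generation = NA_integer_, ancestry_fraction = frac,
                 short_sample = FALSE),
            class = "ancestry_sample")
}

#' Write a run manifest
#'
#' Records the resolved configuration and seed of a run as JSON so the
#' full pipeline can be reproduced bit-for-bit.
#'
#' @param config A named list of parameters (must include any seed used).
#' @param path Output JSON path.
#' @export
write_manifest <- function(config, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing a manifest requires the 'jsonlite' package")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
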