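# MVB-fraction proteomics post-processing: PSM abundance filtering and
# log2 fold-change enrichment listing.

#' Read a proteomics table (TSV)
#'
#' Expected columns: protein_id, unique_peptides, psm, intensity_mvb,
#' intensity_lysate.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_proteomics_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "unique_peptides", "psm", "intensity_mvb",
            "intensity_lysate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$psm < 0) || any(df$psm != round(df$psm)))
    stop("psm must be non-negative integers")
  df
}

#' Discard low-abundance proteins (PSM below a floor)
#'
#' The published filter: proteins with PSM < 10 are disregarded (from
#' both the MVB fraction and the lysate control); a PSM of exactly 10 is
#' kept. The number removed is reported as an attribute.
#'
#' @param rows proteomics data.frame with a \code{psm} column.
#' @param min_psm abundance floor (default 10).
#' @return filtered data.frame with attribute \code{n_removed}.
#' @export
filter_low_abundance <- function(rows, min_psm = 10) {
  keep <- rows$psm >= min_psm
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Log2 fold-change enrichment (MVB fraction vs lysate)
#'
#' \code{log2FC = log2((I_mvb + eps) / (I_lysate + eps))}; a protein is
#' enriched iff log2FC exceeds 1 strictly. The default pseudocount is
#' half the smallest nonzero intensity in the table (0 when
#' \code{pseudocount = 0} and both intensities are positive); rows with
#' both intensities zero are flagged not-quantified (log2FC = NA).
#'
#' @param rows proteomics data.frame (\code{intensity_mvb},
#'   \code{intensity_lysate} columns, values >= 0).
#' @param pseudocount epsilon added to both intensities; \code{NULL} (the
#'   default) uses half the smallest nonzero intensity.
#' @return data.frame with added \code{log2fc}, \code{enriched},
#'   \code{quantified} columns.
#' @export
enrich_log2fc <- function(rows, pseudocount = NULL) {
  a <- rows$intensity_mvb; b <- rows$intensity_lysate
  if (any(a < 0) || any(b < 0)) stop("intensities must be >= 0")
  if (is.null(pseudocount)) {
    nz <- c(a[a > 0], b[b > 0])
    pseudocount <- if (length(nz)) min(nz) / 2 else 0
  }
  quantified <- !(a == 0 & b == 0)
  lfc <- rep(NA_real_, length(a))
  ok <- quantified & (a + pseudocount > 0) & (b + pseudocount > 0)
  lfc[ok] <- log2((a[ok] + pseudocount) / (b[ok] + pseudocount))
  rows$log2fc <- lfc
  rows$enriched <- !is.na(lfc) & lfc > 1
  rows$quantified <- quantified
  rows
}

#' Write the enrichment table as TSV
#' @param rows data.frame from \code{\link{enrich_log2fc}}
#' @param path output path
#' @export
write_proteomics_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
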