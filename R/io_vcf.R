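#' Read a window of phased haplotypes from a VCF
#'
#' Extracts phased diploid genotypes in a genomic window and polarizes
#' alleles against an ancestral (outgroup) source, producing one row per
#' haplotype (two per sample) with 1 = derived (non-ancestral) allele.
#' Sites are dropped, with a logged reason, when they are multi-allelic,
#' unphased or partially missing, or when the ancestral state is unknown
#' or matches neither allele. An explicit ancestral table takes precedence
#' over the VCF `AA` INFO tag; with neither available the call errors, as
#' HAF scores require polarized alleles.
#'
#' @param path Path to a VCF (4.x, plain text or bgzipped).
#' @param chrom Chromosome name as written in the VCF.
#' @param start,end 1-based inclusive window bounds, or
#' @param center,flank alternative window specification: `center +/- flank`
#'   (default flank 25000 gives the 50 kb windows used around favored
#'   sites).
#' @param ancestral Either a data frame with columns `pos` and `allele`
#'   (ancestral base per position) or the string `"AA"` to read the VCF
#'   `AA` INFO tag.
#' @param quiet Suppress the per-reason drop log.
#' @return A [hap_matrix()] with haplotype ids `<sample>_1` / `<sample>_2`.
#' @export
read_vcf_window <- function(path, chrom, start = NULL, end = NULL,
                            center = NULL, flank = 25000,
                            ancestral = NULL, quiet = FALSE) {
  if (!is.null(center)) {
    start <- center - flank
    end <- center + flank
  }
  if (is.null(start) || is.null(end) || start > end) {
    stop("invalid window: give start <= end or center/flank", call. = FALSE)
  }
  if (is.null(ancestral)) {
    stop("an ancestral-allele source is required (outgroup table or 'AA')",
         call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- as.numeric(fix[, "POS"])
  keep <- fix[, "CHROM"] == chrom & pos >= start & pos <= end
  drop_log <- c(multiallelic = 0L, unphased_or_missing = 0L,
                no_ancestral = 0L, ancestral_mismatch = 0L)
  if (!any(keep)) {
    stop("no sites in window ", chrom, ":", start, "-", end, call. = FALSE)
  }
  v <- v[keep, ]
  fix <- matrix(vcfR::getFIX(v), ncol = ncol(fix),
                dimnames = list(NULL, colnames(fix)))
  pos <- as.numeric(fix[, "POS"])
  gt <- vcfR::extract.gt(v)
  S <- nrow(gt)
  samples <- colnames(gt)

  anc <- rep(NA_character_, S)
  if (is.character(ancestral) && length(ancestral) == 1 &&
      ancestral == "AA") {
    aa <- vcfR::extract.info(v, element = "AA")
    anc <- toupper(aa)
  } else {
    anc_tab <- as.data.frame(ancestral)
    stopifnot(all(c("pos", "allele") %in% names(anc_tab)))
    hit <- match(pos, anc_tab$pos)
    anc <- toupper(anc_tab$allele[hit])
  }
  anc[anc %in% c(".", "N", "-", "")] <- NA_character_

  rows <- 2L * length(samples)
  mat_cols <- list()
  col_pos <- numeric(0)
  for (j in seq_len(S)) {
    if (grepl(",", fix[j, "ALT"], fixed = TRUE)) {
      drop_log["multiallelic"] <- drop_log["multiallelic"] + 1L
      next
    }
    g <- gt[j, ]
    if (any(is.na(g)) || !all(grepl("^[01]\\|[01]$", g))) {
      drop_log["unphased_or_missing"] <- drop_log["unphased_or_missing"] + 1L
      next
    }
    if (is.na(anc[j])) {
      drop_log["no_ancestral"] <- drop_log["no_ancestral"] + 1L
      next
    }
    ref <- toupper(fix[j, "REF"])
    alt <- toupper(fix[j, "ALT"])
    if (anc[j] == ref) {
      flip <- FALSE
    } else if (anc[j] == alt) {
      flip <- TRUE
    } else {
      warning("site ", chrom, ":", pos[j],
              ": ancestral allele matches neither REF nor ALT; dropped",
              call. = FALSE)
      drop_log["ancestral_mismatch"] <- drop_log["ancestral_mismatch"] + 1L
      next
    }
    bits <- as.integer(unlist(strsplit(g, "|", fixed = TRUE)))
    if (flip) bits <- 1L - bits
    mat_cols[[length(mat_cols) + 1L]] <- bits
    col_pos <- c(col_pos, pos[j])
  }
  if (!quiet) {
    kept <- length(mat_cols)
    message("read_vcf_window: kept ", kept, " of ", S, " sites (dropped ",
            paste(paste0(names(drop_log)[drop_log > 0], "=",
                         drop_log[drop_log > 0]), collapse = ", "),
            if (all(drop_log == 0)) "none", ")")
  }
  if (!length(mat_cols)) {
    stop("no usable phased, polarized sites in window", call. = FALSE)
  }
  m <- do.call(cbind, mat_cols)
  ids <- as.vector(t(outer(samples, c("_1", "_2"), paste0)))
  hap_matrix(m, positions = col_pos, sample_ids = ids)
}
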