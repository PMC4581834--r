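#' Phased binary haplotype matrix
#'
#' Container for a sample of `n` phased haplotypes typed at `S` biallelic
#' sites, with alleles polarized so that 0 is ancestral and 1 is derived.
#' Rows are haplotypes, columns are sites. Positions are base-pair
#' coordinates and must be strictly increasing.
#'
#' @param data Matrix (or object coercible to one) with entries in `{0, 1}`;
#'   one row per haplotype, one column per site.
#' @param positions Numeric vector of site coordinates in base pairs, one per
#'   column, strictly increasing. Defaults to `1:S`.
#' @param sample_ids Character vector of haplotype labels. Defaults to
#'   `"hap_1" ... "hap_n"`.
#' @param carrier_truth Optional logical (or `"carrier"`/`"non-carrier"`)
#'   vector marking haplotypes known to carry the favored allele, for
#'   evaluating carrier predictions against simulation truth.
#'
#' @return An object of class `hap_matrix`: an integer matrix with
#'   `positions`, `sample_ids` and optional `carrier_truth` attributes.
#' @examples
#' h <- hap_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0), c(0, 0, 0)))
#' haf_score(h)
#' @export
hap_matrix <- function(data, positions = NULL, sample_ids = NULL,
                       carrier_truth = NULL) {
  data <- as.matrix(data)
  bad <- which(!(data %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(data)) + 1
    j <- ((bad[1] - 1) %/% nrow(data)) + 1
    stop("non-binary entry at row ", i, ", column ", j,
         ": haplotype data must be 0 (ancestral) or 1 (derived)",
         call. = FALSE)
  }
  storage.mode(data) <- "integer"
  n <- nrow(data)
  S <- ncol(data)
  if (is.null(positions)) positions <- seq_len(S)
  if (length(positions) != S) {
    stop("length(positions) must equal the number of sites", call. = FALSE)
  }
  if (S > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (n) paste0("hap_", seq_len(n)) else character(0)
  }
  if (length(sample_ids) != n) {
    stop("length(sample_ids) must equal the number of haplotypes",
         call. = FALSE)
  }
  if (!is.null(carrier_truth)) {
    if (is.character(carrier_truth)) {
      carrier_truth <- carrier_truth == "carrier"
    }
    carrier_truth <- as.logical(carrier_truth)
    if (length(carrier_truth) != n) {
      stop("length(carrier_truth) must equal the number of haplotypes",
           call. = FALSE)
    }
  }
  structure(data,
            positions = as.numeric(positions),
            sample_ids = as.character(sample_ids),
            carrier_truth = carrier_truth,
            class = c("hap_matrix", "matrix", "array"))
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", nrow(x), " haplotypes x ", ncol(x), " sites\n",
      sep = "")
  if (!is.null(attr(x, "carrier_truth"))) {
    cat("  carrier truth: ", sum(attr(x, "carrier_truth")), " carriers\n",
        sep = "")
  }
  if (ncol(x)) {
    p <- attr(x, "positions")
    cat("  positions: ", format(p[1], big.mark = ","), " .. ",
        format(p[length(p)], big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' @export
`[.hap_matrix` <- function(x, i, j, ...) {
  m <- unclass(x)
  attr(m, "positions") <- NULL
  attr(m, "sample_ids") <- NULL
  attr(m, "carrier_truth") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  ct <- attr(x, "carrier_truth")
  hap_matrix(m[i, j, drop = FALSE],
             positions = attr(x, "positions")[j],
             sample_ids = attr(x, "sample_ids")[i],
             carrier_truth = if (!is.null(ct)) ct[i])
}

#' Drop sites that are not polymorphic in the sample
#'
#' Removes sites whose derived-allele count is 0 or `n`: a mutation carried
#' by none or all sampled haplotypes is invisible to HAF scoring. Column
#' order is preserved. The number of sites removed is reported via
#' `message()`.
#'
#' @param x A [hap_matrix()].
#' @param quiet Suppress the log message.
#' @return A `hap_matrix` containing only sites with derived count
#'   `1 <= w <= n - 1`.
#' @export
filter_polymorphic <- function(x, quiet = TRUE) {
  stopifnot(inherits(x, "hap_matrix"))
  n <- nrow(x)
  if (ncol(x) == 0L) return(x)
  w <- colSums(x)
  keep <- w >= 1L & w <= n - 1L
  if (!quiet && any(!keep)) {
    message("filter_polymorphic: dropped ", sum(!keep),
            " monomorphic site(s) of ", ncol(x))
  }
  x[, keep]
}
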