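#' Read ms-style simulator output
#'
#' Parses the text format shared by ms, msms and kin: replicates delimited
#' by `//`, each with a `segsites:` count, a `positions:` line of fractions
#' in `[0, 1]`, and one `0/1` row per haplotype. Positions are scaled to
#' base pairs by `window_length`. A sidecar truth file (JSON mapping
#' `sample_id` to `"carrier"`/`"non-carrier"`, one object per replicate) is
#' merged into `carrier_truth` when supplied.
#'
#' @param path Path to the ms-style text file.
#' @param window_length Window length in bp used to scale the fractional
#'   positions (default 50000).
#' @param truth Optional path to a sidecar truth JSON.
#' @return A list of [hap_matrix()] objects, one per replicate.
#' @export
read_ms <- function(path, window_length = 50000, truth = NULL) {
  lines <- readLines(path)
  starts <- which(lines == "//" | startsWith(lines, "//"))
  if (!length(starts)) {
    stop("no '//' replicate delimiter found in ", path, call. = FALSE)
  }
  truth_list <- NULL
  if (!is.null(truth)) {
    truth_list <- jsonlite::read_json(truth)
    if (!is.null(names(truth_list))) truth_list <- list(truth_list)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    seg_i <- grep("^segsites:", block)
    if (!length(seg_i)) {
      stop("replicate ", b, " (line ", starts[b],
           "): missing 'segsites:' line", call. = FALSE)
    }
    S <- as.integer(sub("^segsites:\\s*", "", block[seg_i[1]]))
    if (is.na(S)) {
      stop("replicate ", b, ": unparsable segsites count", call. = FALSE)
    }
    if (S == 0L) {
      rows_i <- integer(0)
      pos <- numeric(0)
      # haplotype count unknown for an empty block; emit 0 x 0
      m <- matrix(0L, 0L, 0L)
    } else {
      pos_i <- grep("^positions:", block)
      if (!length(pos_i)) {
        stop("replicate ", b, ": missing 'positions:' line", call. = FALSE)
      }
      pos <- as.numeric(strsplit(
        trimws(sub("^positions:\\s*", "", block[pos_i[1]])), "\\s+")[[1]])
      if (length(pos) != S) {
        stop("replicate ", b, ": ", length(pos), " positions for ", S,
             " segregating sites", call. = FALSE)
      }
      rows_i <- which(grepl("^[01]+$", block))
      rows_i <- rows_i[rows_i > pos_i[1]]
      if (!length(rows_i)) {
        stop("replicate ", b, ": no haplotype rows", call. = FALSE)
      }
      rows <- block[rows_i]
      if (any(nchar(rows) != S)) {
        bad <- which(nchar(rows) != S)[1]
        stop("replicate ", b, ", haplotype row ", bad, " (line ",
             starts[b] + rows_i[bad] - 1L, "): row length ",
             nchar(rows[bad]), " != segsites ", S, call. = FALSE)
      }
      m <- matrix(as.integer(charToRaw(paste(rows, collapse = ""))) - 48L,
                  nrow = length(rows), ncol = S, byrow = TRUE)
      pos <- pos * window_length
      if (S > 1 && any(diff(pos) <= 0)) {
        # printed precision can tie adjacent positions; spread minimally
        pos <- cummax(pos) + seq_len(S) * 1e-9
      }
    }
    ct <- NULL
    ids <- NULL
    if (!is.null(truth_list) && b <= length(truth_list)) {
      tb <- unlist(truth_list[[b]])
      ids <- names(tb)
      ct <- unname(tb) == "carrier"
      if (nrow(m) > 0 && length(ct) != nrow(m)) {
        stop("replicate ", b, ": truth sidecar has ", length(ct),
             " entries for ", nrow(m), " haplotypes", call. = FALSE)
      }
    }
    out[[b]] <- hap_matrix(m, positions = pos, sample_ids = ids,
                           carrier_truth = ct)
  }
  out
}

#' Write samples as ms-style text
#'
#' Inverse of [read_ms()]: writes one `//` block per sample with
#' `segsites:` and fractional `positions:` lines. When any sample carries
#' `carrier_truth`, a sidecar JSON (`<path>.truth.json`) records the labels.
#'
#' @param samples A [hap_matrix()] or list of them.
#' @param path Output file path.
#' @param window_length Window length in bp used to express positions as
#'   fractions.
#' @return `path`, invisibly.
#' @export
write_ms <- function(samples, path, window_length = 50000) {
  if (inherits(samples, "hap_matrix")) samples <- list(samples)
  n <- if (length(samples)) nrow(samples[[1]]) else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ms", n, length(samples)), "0 0 0", ""), con)
  truth <- list()
  has_truth <- FALSE
  for (s in samples) {
    stopifnot(inherits(s, "hap_matrix"))
    writeLines("//", con)
    writeLines(paste0("segsites: ", ncol(s)), con)
    if (ncol(s)) {
      frac <- attr(s, "positions") / window_length
      writeLines(paste0("positions: ",
                        paste(formatC(frac, format = "f", digits = 8),
                              collapse = " ")), con)
      writeLines(apply(unclass(s), 1, paste, collapse = ""), con)
    }
    writeLines("", con)
    ct <- attr(s, "carrier_truth")
    if (!is.null(ct)) {
      has_truth <- TRUE
      lab <- ifelse(ct, "carrier", "non-carrier")
      names(lab) <- attr(s, "sample_ids")
      truth[[length(truth) + 1L]] <- as.list(lab)
    } else {
      truth[[length(truth) + 1L]] <- stats::setNames(list(), character(0))
    }
  }
  if (has_truth) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
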