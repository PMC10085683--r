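#' Build a contact-pairs table
#'
#' A `contact_pairs` object is a tibble of genomic contact records (one row per
#' ligation pair) carrying the chromosome sizes as an attribute. Positions are
#' 0-based and must satisfy `0 <= pos < chrom_sizes[chrom]`.
#'
#' @param records A data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (extra columns such as `readID`, `strand1`, `strand2` are kept).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A tibble of class `contact_pairs` with an added logical column
#'   `intra` flagging intra-chromosomal records.
#' @export
contact_pairs <- function(records, chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    rlang::abort("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  if (any(chrom_sizes <= 0)) {
    rlang::abort("chromosome lengths must be positive")
  }
  records <- tibble::as_tibble(records)
  needed <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(needed %in% names(records))) {
    rlang::abort(paste0(
      "`records` must have columns ", paste(needed, collapse = ", ")
    ))
  }
  if (nrow(records) > 0) {
    unknown <- setdiff(
      unique(c(records$chrom1, records$chrom2)), names(chrom_sizes)
    )
    if (length(unknown) > 0) {
      rlang::abort(paste0(
        "records reference chromosomes absent from `chrom_sizes`: ",
        paste(unknown, collapse = ", ")
      ))
    }
    bad <- which(
      records$pos1 < 0 | records$pos2 < 0 |
        records$pos1 >= chrom_sizes[records$chrom1] |
        records$pos2 >= chrom_sizes[records$chrom2]
    )
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "record ", bad[1], " (", records$chrom1[bad[1]], ":",
        records$pos1[bad[1]], " - ", records$chrom2[bad[1]], ":",
        records$pos2[bad[1]], ") has a position outside its chromosome"
      ))
    }
  }
  records$intra <- records$chrom1 == records$chrom2
  attr(records, "chrom_sizes") <- chrom_sizes
  class(records) <- c("contact_pairs", class(tibble::tibble()))
  records
}

#' Chromosome sizes of a contact-pairs table
#' @param pairs A `contact_pairs` object.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
chrom_sizes <- function(pairs) {
  cs <- attr(pairs, "chrom_sizes")
  if (is.null(cs)) rlang::abort("object carries no chromosome sizes")
  cs
}

#' Read contacts from a 4DN .pairs file
#'
#' Parses the plain-text (optionally gzip-compressed) `.pairs` dialect with
#' columns `readID chrom1 pos1 chrom2 pos2 strand1 strand2`. Header lines
#' (starting with `#`) are skipped; `#chromsize:` header lines supply the
#' chromosome lengths unless `chrom_sizes` is given explicitly.
#'
#' @param path Path to a `.pairs` or `.pairs.gz` file.
#' @param chrom_sizes Optional named vector of chromosome lengths (bp);
#'   overrides any `#chromsize:` header lines.
#' @return A [contact_pairs] tibble.
#' @export
read_pairs <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  # headers must be a leading block; treat any later '#' line as malformed
  body_start <- if (any(!is_header)) which(!is_header)[1] else length(lines) + 1L
  header <- lines[seq_len(body_start - 1L)]
  body <- if (body_start <= length(lines)) lines[body_start:length(lines)] else character()

  if (is.null(chrom_sizes)) {
    cs_lines <- grep("^#chromsize:", header, value = TRUE)
    if (length(cs_lines) == 0) {
      rlang::abort("no #chromsize: header lines and no `chrom_sizes` supplied")
    }
    fields <- strsplit(sub("^#chromsize:\\s*", "", cs_lines), "\\s+")
    chrom_sizes <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
    names(chrom_sizes) <- vapply(fields, `[`, character(1), 1)
  }

  if (length(body) == 0) {
    recs <- tibble::tibble(
      readID = character(), chrom1 = character(), pos1 = numeric(),
      chrom2 = character(), pos2 = numeric(),
      strand1 = character(), strand2 = character()
    )
    return(contact_pairs(recs, chrom_sizes))
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 7)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed .pairs line ", body_start - 1L + bad[1],
      ": expected 7 tab-separated fields, got ", nf[bad[1]]
    ))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:7)), ncol = 7, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 3]))
  pos2 <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(pos1) | is.na(pos2))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed .pairs line ", body_start - 1L + bad[1],
      ": non-numeric position"
    ))
  }
  recs <- tibble::tibble(
    readID = m[, 1], chrom1 = m[, 2], pos1 = pos1,
    chrom2 = m[, 4], pos2 = pos2, strand1 = m[, 6], strand2 = m[, 7]
  )
  contact_pairs(recs, chrom_sizes)
}

#' Write contacts to a 4DN .pairs file
#'
#' @param pairs A [contact_pairs] tibble.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  cs <- chrom_sizes(pairs)
  header <- c(
    "## pairs format v1.0",
    paste0("#chromsize: ", names(cs), " ", format(cs, scientific = FALSE, trim = TRUE)),
    "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"
  )
  readID <- if ("readID" %in% names(pairs)) pairs$readID else
    sprintf("pair%06d", seq_len(nrow(pairs)))
  strand1 <- if ("strand1" %in% names(pairs)) pairs$strand1 else rep("+", nrow(pairs))
  strand2 <- if ("strand2" %in% names(pairs)) pairs$strand2 else rep("+", nrow(pairs))
  body <- sprintf(
    "%s\t%s\t%s\t%s\t%s\t%s\t%s",
    readID, pairs$chrom1,
    format(pairs$pos1, scientific = FALSE, trim = TRUE),
    pairs$chrom2,
    format(pairs$pos2, scientific = FALSE, trim = TRUE),
    strand1, strand2
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @export
print.contact_pairs <- function(x, ...) {
  cs <- attr(x, "chrom_sizes")
  cat("# contact_pairs: ", nrow(x), " records (",
      sum(x$intra), " intra) on ", length(cs), " chromosome(s)\n", sep = "")
  NextMethod()
}
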