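#' Read a Genepop genotype file
#'
#' Parses the classic Genepop interchange format: a title line, locus names
#' (one per line or comma-separated on one line), then population blocks
#' separated by lines equal to `Pop` (case-insensitive). Sample lines are
#' `id , g1 g2 ...` with alleles encoded in fixed 2- or 3-digit fields;
#' all-zero codes are missing data.
#'
#' @param path file path, or a character vector of lines (for streams built
#'   in memory).
#' @param pop_names optional character vector overriding population names;
#'   by default the last sample id of each block names its population, per
#'   Genepop convention.
#' @return a [genotype_table()] whose `population` column holds the block
#'   names.
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE)
           else as.character(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) stop("genepop parse error: file too short")
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("genepop parse error: no 'Pop' line found")
  locus_lines <- trimws(body[seq_len(first_pop - 1)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("genepop parse error: no locus names before first 'Pop'")

  pop_breaks <- which(is_pop)
  ids <- character(); pops_idx <- integer(); rows <- list()
  digits <- NA_integer_
  cur_pop <- 0L
  for (j in seq_along(body)) {
    ln <- body[j]
    if (is_pop[j]) { cur_pop <- cur_pop + 1L; next }
    if (!nzchar(trimws(ln)) || cur_pop == 0L) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("genepop parse error at line %d: no comma after sample id",
                   j + 1L))
    }
    id <- trimws(parts[1])
    gfields <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "[[:space:]]+")[[1]]
    gfields <- gfields[nzchar(gfields)]
    if (length(gfields) != length(loci)) {
      stop(sprintf(
        "genepop parse error at line %d: %d genotype fields for %d loci",
        j + 1L, length(gfields), length(loci)))
    }
    w <- unique(nchar(gfields))
    if (length(w) != 1 || !(w %in% c(4L, 6L))) {
      stop(sprintf(
        "genepop parse error at line %d: allele fields must be uniformly 4 or 6 digits",
        j + 1L))
    }
    d <- w / 2L
    if (is.na(digits)) digits <- d
    if (d != digits) {
      stop(sprintf("genepop parse error at line %d: mixed allele encodings",
                   j + 1L))
    }
    a <- as.integer(substr(gfields, 1L, digits))
    b <- as.integer(substr(gfields, digits + 1L, 2L * digits))
    if (anyNA(a) || anyNA(b)) {
      stop(sprintf("genepop parse error at line %d: non-numeric allele field",
                   j + 1L))
    }
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    ids <- c(ids, id); pops_idx <- c(pops_idx, cur_pop)
    rows[[length(rows) + 1L]] <- cbind(a, b)
  }
  if (!length(rows)) stop("genepop parse error: no sample lines")
  n <- length(rows)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2))
  for (i in seq_len(n)) calls[i, , ] <- rows[[i]]
  block_names <- if (!is.null(pop_names)) {
    if (length(pop_names) != max(pops_idx)) {
      stop("pop_names must have one entry per population block")
    }
    pop_names
  } else {
    vapply(seq_len(max(pops_idx)), function(p) ids[max(which(pops_idx == p))],
           character(1))
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  genotype_table(
    samples = data.frame(sample_id = ids,
                         population = block_names[pops_idx],
                         stringsAsFactors = FALSE),
    loci = loci, calls = calls)
}

#' Write a genotype table in Genepop format
#'
#' @param table a [genotype_table()].
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @param digits allele field width per allele, 2 or 3 (default 3:
#'   microsatellite fragment sizes exceed 99).
#' @param title title line content.
#' @return invisibly, the character vector of lines written.
#' @export
write_genepop <- function(table, path = NULL, digits = 3, title = "grousepop export") {
  stopifnot(inherits(table, "genotype_table"), digits %in% c(2, 3))
  if (n_loci(table) == 0) stop("cannot write a table with no loci")
  mx <- suppressWarnings(max(table$calls, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits) {
    stop(sprintf("allele code %d does not fit in %d digits", mx, digits))
  }
  fmt <- function(v) {
    v[is.na(v)] <- 0L
    sprintf(paste0("%0", digits, "d"), v)
  }
  pops <- table$samples$population
  pops[is.na(pops)] <- "NA"
  blocks <- unique(pops)
  out <- c(title, table$loci)
  for (p in blocks) {
    out <- c(out, "Pop")
    for (i in which(pops == p)) {
      g <- paste0(fmt(table$calls[i, , 1]), fmt(table$calls[i, , 2]))
      out <- c(out, paste0(table$samples$sample_id[i], " ,  ",
                           paste(g, collapse = " ")))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
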