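#' Write / read a genotype table as delimited text
#'
#' The tabular dialect is tab-separated with a documented header: the seven
#' metadata columns (`sample_id`, `individual_id`, `population`,
#' `lineage_prior`, `sex`, `locality`, `source`) followed by one column per
#' locus holding `a/b` allele pairs; missing calls are empty fields or `NA`.
#'
#' @param table a [genotype_table()].
#' @param path output path (write) / input path (read).
#' @return `write_genotype_table()` returns `path` invisibly;
#'   `read_genotype_table()` returns a [genotype_table()].
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  meta_cols <- c("sample_id", "individual_id", "population", "lineage_prior",
                 "sex", "locality", "source")
  df <- table$samples[, meta_cols]
  for (l in seq_len(n_loci(table))) {
    a <- table$calls[, l, 1]; b <- table$calls[, l, 2]
    df[[table$loci[l]]] <- ifelse(is.na(a), "", paste0(a, "/", b))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  meta_cols <- c("sample_id", "individual_id", "population", "lineage_prior",
                 "sex", "locality", "source")
  missing_meta <- setdiff("sample_id", names(df))
  if (length(missing_meta)) stop("tabular genotype file lacks sample_id column")
  loci <- setdiff(names(df), meta_cols)
  n <- nrow(df)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2))
  for (l in seq_along(loci)) {
    v <- df[[loci[l]]]
    ok <- !is.na(v) & nzchar(v)
    if (any(ok)) {
      parts <- strsplit(v[ok], "/", fixed = TRUE)
      if (any(lengths(parts) != 2)) {
        stop(sprintf("malformed allele pair in locus %s", loci[l]))
      }
      m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
      calls[which(ok), l, 1] <- m[, 1]
      calls[which(ok), l, 2] <- m[, 2]
    }
  }
  meta <- df[intersect(meta_cols, names(df))]
  sx <- meta$sex
  if (!is.null(sx)) meta$sex[is.na(sx)] <- "unknown"
  genotype_table(meta, loci, calls)
}

#' Write / read the clustering-stage integer matrix format
#'
#' Two rows per individual (one per gene copy), one column per locus,
#' missing coded `-9`; first column the sample id, optional second column an
#' integer `popinfo` derived from `lineage_prior`.
#'
#' @param table a [genotype_table()].
#' @param path output path (or `NULL` for lines).
#' @param popinfo include the lineage-prior column?
#' @return `write_cluster_matrix()`: invisibly the lines;
#'   `read_cluster_matrix()`: a [genotype_table()] (lineage priors restored
#'   from the legend comment when present).
#' @export
write_cluster_matrix <- function(table, path = NULL, popinfo = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  prior <- table$samples$lineage_prior
  have_prior <- popinfo && any(!is.na(prior))
  levels_prior <- if (have_prior) sort(unique(prior[!is.na(prior)])) else character()
  code <- if (have_prior) {
    p <- match(prior, levels_prior); p[is.na(p)] <- 0L; p
  } else NULL
  hdr <- paste(c("id", if (have_prior) "popinfo", table$loci), collapse = "\t")
  legend <- if (have_prior) {
    paste0("# popinfo: ", paste(sprintf("%d=%s", seq_along(levels_prior),
                                        levels_prior), collapse = ", "))
  } else NULL
  out <- c(legend, hdr)
  for (i in seq_len(n_samples(table))) {
    for (copy in 1:2) {
      v <- table$calls[i, , copy]
      v[is.na(v)] <- -9L
      out <- c(out, paste(c(table$samples$sample_id[i],
                            if (have_prior) code[i], v), collapse = "\t"))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' @rdname write_cluster_matrix
#' @export
read_cluster_matrix <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE)
           else as.character(path)
  legend <- grep("^# popinfo:", lines, value = TRUE)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  have_prior <- length(hdr) >= 2 && hdr[2] == "popinfo"
  loci <- hdr[-(1:(1 + have_prior))]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) %% 2 != 0) stop("cluster matrix must have two rows per individual")
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(body) / 2
  ids <- character(n); prior_code <- integer(n)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2))
  for (i in seq_len(n)) {
    r1 <- fields[[2 * i - 1]]; r2 <- fields[[2 * i]]
    if (r1[1] != r2[1]) stop("cluster matrix rows for one individual must share an id")
    ids[i] <- r1[1]
    if (have_prior) prior_code[i] <- as.integer(r1[2])
    off <- 1 + have_prior
    a <- as.integer(r1[-seq_len(off)]); b <- as.integer(r2[-seq_len(off)])
    a[a == -9L] <- NA_integer_; b[b == -9L] <- NA_integer_
    calls[i, , 1] <- a; calls[i, , 2] <- b
  }
  prior <- rep(NA_character_, n)
  if (have_prior && length(legend)) {
    map <- sub("^# popinfo: ", "", legend[1])
    kv <- strsplit(strsplit(map, ", ", fixed = TRUE)[[1]], "=", fixed = TRUE)
    lv <- vapply(kv, `[`, character(1), 2)
    names(lv) <- vapply(kv, `[`, character(1), 1)
    prior[prior_code > 0L] <- lv[as.character(prior_code[prior_code > 0L])]
  }
  genotype_table(data.frame(sample_id = ids, lineage_prior = prior,
                            stringsAsFactors = FALSE),
                 loci, calls)
}
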