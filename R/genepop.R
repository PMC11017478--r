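# GENEPOP flat-file input/output for diploid genotype tables.

#' Read a GENEPOP genotype file
#'
#' Supports the standard layout: a title line, locus names (one per line or
#' comma-separated), and `POP` sections whose individual lines are
#' `name , g1 g2 ...` with 2-digit or 3-digit allele codes per gene copy
#' (`0000`/`000000` or `00`/`000` per copy denotes missing). The population
#' label is taken from the name field of the first individual in each `POP`
#' section, the convention used by most GENEPOP writers.
#'
#' @param path Path to a GENEPOP file.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a GENEPOP file: too few lines")
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP section found")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("no locus names found")

  sections <- split(body[!is_pop], cumsum(is_pop)[!is_pop])
  sections <- sections[names(sections) != "0"]  # "0" holds the locus block
  ind <- character(0); pop <- character(0); rows <- list()
  digits <- NULL
  for (s in sections) {
    parts <- strsplit(s, ",")
    plabel <- trimws(parts[[1]][1])
    if (!nzchar(plabel)) plabel <- paste0("pop", length(unique(pop)) + 1)
    for (i in seq_along(s)) {
      nm <- trimws(parts[[i]][1])
      geno <- trimws(paste(parts[[i]][-1], collapse = " "))
      codes <- strsplit(geno, "[[:space:]]+")[[1]]
      codes <- codes[nzchar(codes)]
      if (length(codes) != length(loci))
        stop("individual '", nm, "' has ", length(codes),
             " genotypes for ", length(loci), " loci")
      w <- nchar(codes[1])
      if (!w %in% c(4L, 6L)) stop("allele codes must be 4 or 6 digits wide")
      if (is.null(digits)) digits <- w / 2
      a1 <- as.integer(substr(codes, 1, digits))
      a2 <- as.integer(substr(codes, digits + 1, 2 * digits))
      a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
      miss <- is.na(a1) | is.na(a2)
      a1[miss] <- NA; a2[miss] <- NA
      ind <- c(ind, if (nzchar(nm)) nm else paste0(plabel, "_", i))
      pop <- c(pop, plabel)
      rows[[length(rows) + 1]] <- cbind(a1, a2)
    }
  }
  arr <- array(NA_integer_, dim = c(length(ind), length(loci), 2),
               dimnames = list(NULL, loci, NULL))
  for (i in seq_along(rows)) {
    arr[i, , 1] <- rows[[i]][, 1]
    arr[i, , 2] <- rows[[i]][, 2]
  }
  genotype_table(ind, pop, arr)
}

#' Write a genotype table in GENEPOP format
#'
#' @param x A [genotype_table()].
#' @param path Output file path.
#' @param digits Width of a single allele code, 2 or 3.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, digits = 3, title = "cavecharr export") {
  if (!digits %in% c(2, 3)) stop("digits must be 2 or 3")
  amax <- suppressWarnings(max(x$alleles, na.rm = TRUE))
  if (is.finite(amax) && amax >= 10^digits)
    stop("allele codes exceed ", digits, "-digit width")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  for (p in levels(x$pop)) {
    writeLines("POP", con)
    idx <- which(x$pop == p)
    for (i in idx) {
      codes <- paste0(fmt(x$alleles[i, , 1]), fmt(x$alleles[i, , 2]))
      writeLines(paste0(p, " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}
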