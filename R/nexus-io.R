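#' Read a NEXUS alignment with its character sets
#'
#' Parses a DATA or CHARACTERS block (sequential or interleaved) plus a SETS
#' block with `CHARSET` statements and an optional `EXSET` (exclusion set).
#' NEXUS ranges are 1-based inclusive and may use the step notation `a-b\3`
#' and the open end `a-.`; they are materialised as plain 1-based index
#' vectors. Sequence symbols are upper-cased.
#'
#' @param path path to a NEXUS file.
#' @param fragments character vector of charset names to treat as gene
#'   fragments, or `TRUE` to treat every charset that passes the whole-codon
#'   frame check as a fragment (the default), or `FALSE` for none.
#' @param exclusion_charset optionally, the name of a charset to use as the
#'   exclusion mask (in addition to any EXSET statement).
#' @return a [nuc_matrix()].
#' @export
read_nexus <- function(path, fragments = TRUE, exclusion_charset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip NEXUS comments
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file: ", path, call. = FALSE)

  ntax <- nexus_number(txt, "NTAX")
  nchar_decl <- nexus_number(txt, "NCHAR")

  block <- nexus_block(txt, c("DATA", "CHARACTERS"))
  if (is.null(block)) stop("no DATA/CHARACTERS block found", call. = FALSE)
  mx <- regmatches(block,
                   regexpr("(?is)MATRIX\\s.*?;", block, perl = TRUE))
  if (!length(mx)) stop("no MATRIX statement found", call. = FALSE)
  body <- sub("(?is)^MATRIX\\s", "", mx, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n", fixed = TRUE)[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]

  seqs <- list()
  order_seen <- character(0)
  for (row in rows) {
    # label may be quoted; sequence may contain spaces (strip them)
    if (startsWith(row, "'")) {
      m2 <- regmatches(row, regexec("^'([^']*)'\\s+(.*)$", row))[[1]]
    } else {
      m2 <- regmatches(row, regexec("^(\\S+)\\s+(.*)$", row))[[1]]
    }
    if (length(m2) != 3)
      stop("cannot parse matrix row: ", substr(row, 1, 40), call. = FALSE)
    lab <- m2[2]
    seq <- toupper(gsub("\\s", "", m2[3]))
    if (!lab %in% order_seen) {
      order_seen <- c(order_seen, lab)
      seqs[[lab]] <- seq
    } else {
      # interleaved continuation
      seqs[[lab]] <- paste0(seqs[[lab]], seq)
    }
  }
  interleaved <- grepl("(?i)INTERLEAVE", block, perl = TRUE)
  if (!interleaved && anyDuplicated(rows_labels <- order_seen) == 0 &&
      length(rows) > length(order_seen))
    stop("input error: duplicate taxon label in sequential matrix",
         call. = FALSE)
  taxa <- order_seen
  seqv <- unlist(seqs[taxa], use.names = FALSE)
  if (!is.null(ntax) && length(taxa) != ntax)
    warning("NTAX (", ntax, ") differs from rows read (", length(taxa), ")")
  nc <- nchar(seqv[1])
  if (any(nchar(seqv) != nc))
    stop("alignment error: ragged rows in NEXUS matrix", call. = FALSE)
  if (!is.null(nchar_decl) && nc != nchar_decl)
    warning("NCHAR (", nchar_decl, ") differs from columns read (", nc, ")")

  charsets <- list()
  exclusion <- integer(0)
  sets <- nexus_block(txt, "SETS")
  if (!is.null(sets)) {
    for (st in nexus_statements(sets, "CHARSET")) {
      charsets[[st$name]] <- nexus_range(st$value, nc, st$name)
    }
    for (st in nexus_statements(sets, "EXSET")) {
      exclusion <- sort(unique(c(exclusion, nexus_range(st$value, nc,
                                                        st$name))))
    }
  }
  if (!is.null(exclusion_charset)) {
    if (!exclusion_charset %in% names(charsets))
      stop("metadata error: exclusion charset '", exclusion_charset,
           "' not found", call. = FALSE)
    exclusion <- sort(unique(c(exclusion, charsets[[exclusion_charset]])))
  }

  frag_names <- character(0)
  if (isTRUE(fragments)) {
    pos <- rep_len(1:3, nc)
    taken <- integer(0)
    for (nm in names(charsets)) {
      idx <- charsets[[nm]]
      ok <- length(idx) > 0 && length(idx) %% 3L == 0L &&
        all(pos[idx] == rep_len(1:3, length(idx))) &&
        !length(intersect(idx, taken))
      if (ok) {
        frag_names <- c(frag_names, nm)
        taken <- c(taken, idx)
      }
    }
  } else if (is.character(fragments)) {
    frag_names <- fragments
  }

  nuc_matrix(taxa, seqv, charsets = charsets, exclusion = exclusion,
             fragments = frag_names)
}

nexus_number <- function(txt, key) {
  m <- regmatches(txt, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"), txt,
                               perl = TRUE))
  if (!length(m)) return(NULL)
  as.integer(sub(".*=\\s*", "", m))
}

nexus_block <- function(txt, names) {
  for (nm in names) {
    pat <- paste0("(?is)BEGIN\\s+", nm, "\\s*;.*?END\\s*;")
    m <- regmatches(txt, regexpr(pat, txt, perl = TRUE))
    if (length(m)) return(m)
  }
  NULL
}

nexus_statements <- function(block, keyword) {
  pat <- paste0("(?is)", keyword, "\\s+(\\S+?)\\s*=\\s*([^;]*);")
  starts <- gregexpr(pat, block, perl = TRUE)[[1]]
  if (starts[1] == -1) return(list())
  out <- list()
  for (m in regmatches(block, gregexpr(pat, block, perl = TRUE))[[1]]) {
    g <- regmatches(m, regexec(pat, m, perl = TRUE))[[1]]
    nm <- sub("^\\*\\s*", "", g[2])   # "EXSET * name" style
    out[[length(out) + 1L]] <- list(name = nm, value = trimws(g[3]))
  }
  out
}

# Materialise a NEXUS 1-based inclusive range list ("12 40-60 3-9\3 100-.")
nexus_range <- function(value, nc, name) {
  toks <- strsplit(trimws(value), "\\s+")[[1]]
  idx <- integer(0)
  for (tok in toks) {
    step <- 1L
    if (grepl("\\\\", tok)) {
      parts <- strsplit(tok, "\\\\")[[1]]
      tok <- parts[1]
      step <- as.integer(parts[2])
    }
    if (grepl("-", tok, fixed = TRUE)) {
      ab <- strsplit(tok, "-", fixed = TRUE)[[1]]
      a <- as.integer(ab[1])
      b <- if (ab[2] %in% c(".", "")) nc else as.integer(ab[2])
      idx <- c(idx, seq.int(a, b, by = step))
    } else {
      idx <- c(idx, as.integer(tok))
    }
  }
  if (anyNA(idx) || (length(idx) && (min(idx) < 1L || max(idx) > nc)))
    stop("metadata error: charset '", name, "' range out of bounds",
         call. = FALSE)
  sort(unique(idx))
}

#' Write an aligned matrix to NEXUS, FASTA or relaxed PHYLIP
#'
#' NEXUS output is sequential and includes a SETS block with every charset
#' (and an EXSET when the exclusion set is non-empty), so that
#' `read_nexus(write_matrix(m, f, "nexus"))` round-trips taxa, rows, charsets
#' and exclusion losslessly. IUPAC ambiguity codes are written verbatim.
#'
#' @param m a [nuc_matrix()].
#' @param path output file path.
#' @param format one of `"nexus"`, `"fasta"`, `"phylip"`.
#' @param width line-wrap width for FASTA output.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("nexus", "fasta", "phylip"),
                         width = 70L) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "nexus") {
    lab <- nexus_label(m$taxa)
    cat("#NEXUS\n\nBEGIN DATA;\n", file = con)
    cat(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;\n", n_taxa(m), m$n_cols),
        file = con)
    cat("  FORMAT DATATYPE=DNA MISSING=? GAP=-;\n  MATRIX\n", file = con)
    w <- max(nchar(lab)) + 2L
    for (i in seq_along(m$taxa))
      cat(sprintf("  %-*s%s\n", w, lab[i], m$seqs[i]), file = con)
    cat("  ;\nEND;\n", file = con)
    if (length(m$charsets) || length(m$exclusion)) {
      cat("\nBEGIN SETS;\n", file = con)
      for (nm in names(m$charsets))
        cat(sprintf("  CHARSET %s = %s;\n", nm,
                    format_ranges(m$charsets[[nm]])), file = con)
      if (length(m$exclusion))
        cat(sprintf("  EXSET mask = %s;\n", format_ranges(m$exclusion)),
            file = con)
      cat("END;\n", file = con)
    }
  } else if (format == "fasta") {
    for (i in seq_along(m$taxa)) {
      cat(">", m$taxa[i], "\n", sep = "", file = con)
      s <- m$seqs[i]
      starts <- seq.int(1L, max(nchar(s), 1L), by = width)
      cat(paste0(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 collapse = "\n"), "\n", sep = "", file = con)
    }
  } else {
    if (any(grepl("[][():;,[:space:]]", m$taxa)))
      stop("taxon labels illegal for phylip: whitespace or punctuation",
           call. = FALSE)
    cat(sprintf("%d %d\n", n_taxa(m), m$n_cols), file = con)
    w <- max(nchar(m$taxa)) + 2L
    for (i in seq_along(m$taxa))
      cat(sprintf("%-*s%s\n", w, m$taxa[i], m$seqs[i]), file = con)
  }
  invisible(path)
}

nexus_label <- function(taxa) {
  ifelse(grepl("[[:space:]]", taxa), paste0("'", taxa, "'"), taxa)
}

# Compress sorted indices into NEXUS range notation (runs of step 1 only).
format_ranges <- function(idx) {
  if (!length(idx)) return("")
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = " ")
}
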