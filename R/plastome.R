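#' Plastome records
#'
#' A `plastome` bundles one circular chloroplast genome: its sequence, its
#' annotated features, and (once detected) its quadripartite partition.
#' Feature coordinates are 1-based closed intervals on the forward strand;
#' multi-exon features carry one row per part, ordered 5' to 3' on the
#' feature's own strand via the `part` column.
#'
#' @param id Accession or sample id.
#' @param seq DNA string over `A/C/G/T/N` (IUPAC codes accepted).
#' @param taxon Free-text taxon name.
#' @param features Tibble with columns `feature_id`, `name`, `kind`
#'   (`CDS`/`tRNA`/`rRNA`/`pseudogene`/`intron`/`IGR`), `strand` (`+`/`-`),
#'   `part`, `start`, `end`.
#' @param partition Optional tibble with columns `region`
#'   (`LSC`/`IRA`/`SSC`/`IRB`), `start`, `end` (end may exceed the sequence
#'   length for an interval wrapping the circular origin).
#' @return A `plastome` object.
#' @export
plastome <- function(id, seq, taxon = id, features = empty_features(),
                     partition = NULL) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for record ", id, call. = FALSE)
  check_dna(seq, what = paste0("record ", id))
  features <- as_tibble(features)
  n <- nchar(seq)
  if (nrow(features) > 0L) {
    # end may exceed n for a feature wrapping the circular origin
    bad <- features$start < 1L | features$start > n |
      features$start > features$end | (features$end - features$start + 1L) > n
    if (any(bad)) {
      stop("feature coordinates outside [1, ", n, "] in record ", id, call. = FALSE)
    }
  }
  structure(list(id = id, taxon = taxon, seq = seq, features = features,
                 partition = partition, circular = TRUE),
            class = "plastome")
}

empty_features <- function() {
  tibble(feature_id = character(), name = character(), kind = character(),
         strand = character(), part = integer(), start = integer(), end = integer())
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s (%s): %s bp, %d feature part(s)%s\n",
              x$id, x$taxon, format(nchar(x$seq), big.mark = ","),
              nrow(x$features),
              if (is.null(x$partition)) "" else ", partitioned"))
  if (!is.null(x$partition)) {
    p <- x$partition
    cat(paste(sprintf("  %s [%d, %d] (%d bp)", p$region, p$start, p$end,
                      p$end - p$start + 1L), collapse = "\n"), "\n")
  }
  invisible(x)
}

seq_length <- function(rec) nchar(rec$seq)

#' Read plastome sequences and annotations
#'
#' Reads one or more FASTA or GenBank flat files into a list of
#' [plastome()] records. FASTA records carry empty feature tables; GenBank
#' features (`CDS`, `tRNA`, `rRNA`, genes flagged `/pseudo`, introns) are
#' mapped onto the internal feature table, with `join()`/`complement()`
#' locations split into ordered parts.
#'
#' @param paths Character vector of file paths.
#' @param format `"fasta"` or `"genbank"`.
#' @return A named list of `plastome` records (names are record ids).
#' @export
read_plastomes <- function(paths, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("file(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  recs <- purrr::flatten(purrr::map(paths, function(p) {
    if (format == "fasta") read_fasta_records(p) else list(read_genbank_record(p))
  }))
  ids <- vapply(recs, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  setNames(recs, ids)
}

read_fasta_records <- function(path) {
  # readDNAStringSet silently drops invalid letters (warning only); treat
  # both errors and those warnings as parse errors
  ss <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path), error = function(e) {
      stop("parse error in FASTA file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }),
    warning = function(w) {
      stop("parse error in FASTA file ", path, ": ", conditionMessage(w),
           call. = FALSE)
    })
  if (length(ss) == 0L) stop("no sequences in FASTA file ", path, call. = FALSE)
  purrr::map(seq_along(ss), function(i) {
    header <- names(ss)[i]
    id <- sub("\\s.*$", "", header)
    taxon <- sub("^\\S+\\s*", "", header)
    plastome(id = id, seq = as.character(ss[[i]]),
             taxon = if (nzchar(taxon)) taxon else id)
  })
}

# ---- GenBank flat file (read-only, minimal but standard-compliant) ----

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  iv <- purrr::map_dfr(parts, function(p) {
    p <- trimws(p)
    st <- "+"
    if (grepl("^complement\\(", p)) {
      st <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (any(is.na(nums))) stop("unparseable location part: ", p, call. = FALSE)
    if (length(nums) == 1L) nums <- c(nums, nums)
    tibble(start = nums[1], end = nums[2], part_strand = st)
  })
  if (strand == "-") iv$part_strand <- ifelse(iv$part_strand == "-", "+", "-")
  # 5'->3' part order on the feature strand
  feat_strand <- if (all(iv$part_strand == "-")) "-" else "+"
  ord <- if (feat_strand == "-") order(-iv$start) else order(iv$start)
  iv <- iv[ord, ]
  iv$part <- seq_len(nrow(iv))
  list(strand = feat_strand, parts = iv[, c("part", "start", "end")])
}

read_genbank_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) {
    stop("parse error in GenBank file ", path, ": no LOCUS line", call. = FALSE)
  }
  id <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]
  org_i <- grep("^\\s{2}ORGANISM", lines)
  taxon <- if (length(org_i) > 0L) trimws(sub("^\\s+ORGANISM\\s+", "", lines[org_i[1]])) else id
  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) {
    stop("parse error in GenBank file ", path, ": no ORIGIN section", call. = FALSE)
  }
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i) > 0L) end_i[1] else length(lines) + 1L
  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- empty_features()
  if (length(feat_i) > 0L) {
    fl <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    is_key <- grepl("^\\s{5}\\S", fl)
    key_rows <- which(is_key)
    rows <- list()
    for (ki in seq_along(key_rows)) {
      i0 <- key_rows[ki]
      i1 <- if (ki < length(key_rows)) key_rows[ki + 1L] - 1L else length(fl)
      block <- fl[i0:i1]
      key <- sub("^\\s+(\\S+).*$", "\\1", block[1])
      rest <- sub("^\\s+\\S+\\s+", "", block[1])
      body <- c(rest, trimws(block[-1]))
      qual_start <- which(startsWith(body, "/"))
      loc_str <- paste(body[seq_len(if (length(qual_start) > 0L) qual_start[1] - 1L else length(body))],
                       collapse = "")
      quals <- body[startsWith(body, "/")]
      getq <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        gsub('^/[^=]+="?|"$', "", hit[1])
      }
      pseudo <- any(quals == "/pseudo") || any(startsWith(quals, "/pseudo="))
      kind <- switch(key, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     intron = "intron", gene = if (pseudo) "pseudogene" else NA_character_,
                     NA_character_)
      if (is.na(kind)) next
      if (pseudo && kind == "CDS") kind <- "pseudogene"
      loc <- tryCatch(parse_gb_location(loc_str), error = function(e) {
        stop("parse error in GenBank file ", path, " near line ",
             feat_i[1] + i0, ": ", conditionMessage(e), call. = FALSE)
      })
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("standard_name")
      if (is.na(nm)) nm <- getq("product")
      if (is.na(nm)) nm <- paste0(key, "_", length(rows) + 1L)
      fid <- paste0(nm, ".", kind, ".", length(rows) + 1L)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(feature_id = fid, name = nm, kind = kind, strand = loc$strand),
        loc$parts
      )
    }
    if (length(rows) > 0L) feats <- dplyr::bind_rows(rows)
  }
  plastome(id = id, seq = seq, taxon = taxon, features = feats)
}

# ---- GFF3 (read/write) and BED (write) ----

#' Write features to GFF3 / read them back
#'
#' GFF3 output is 1-based closed (the native GFF convention, which matches
#' the package's internal coordinates); multi-part features are written as
#' one row per part sharing an `ID`, so a write/read round trip preserves
#' every part's coordinates and strand.
#'
#' @param rec A [plastome()].
#' @param path Output path.
#' @return `write_gff3()` returns `path` invisibly; `read_gff3()` returns a
#'   feature tibble (see [plastome()]).
#' @export
write_gff3 <- function(rec, path) {
  stopifnot(inherits(rec, "plastome"))
  f <- rec$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", rec$id, seq_length(rec)), con)
  if (nrow(f) > 0L) {
    writeLines(sprintf("%s\tplastdiv\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;part=%d",
                       rec$id, f$kind, f$start, f$end, f$strand,
                       f$feature_id, f$name, f$part), con)
  }
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_features())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    stop("parse error in GFF3 file ", path, " at line ", bad[1], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    v <- sub(paste0("^.*(?:^|;)", key, "=([^;]*).*$"), "\\1", attrs)
    ifelse(grepl(paste0(key, "="), attrs), v, NA_character_)
  }
  out <- tibble(
    feature_id = attr_get(m[, 9], "ID"),
    name = attr_get(m[, 9], "Name"),
    kind = m[, 3],
    strand = m[, 7],
    part = suppressWarnings(as.integer(attr_get(m[, 9], "part"))),
    start = as.integer(m[, 4]),
    end = as.integer(m[, 5])
  )
  out$part[is.na(out$part)] <- 1L
  dplyr::arrange(out, match(.data$feature_id, unique(.data$feature_id)), .data$part)
}

#' Write a quadripartite partition as BED
#'
#' BED uses 0-based half-open coordinates; intervals wrapping the circular
#' origin are split into two BED lines.
#'
#' @param rec A partitioned [plastome()].
#' @param path Output path.
#' @export
write_partition_bed <- function(rec, path) {
  stopifnot(inherits(rec, "plastome"))
  if (is.null(rec$partition)) stop("record has no partition", call. = FALSE)
  n <- seq_length(rec)
  rows <- purrr::map_dfr(seq_len(nrow(rec$partition)), function(i) {
    p <- rec$partition[i, ]
    if (p$end <= n) {
      tibble(chrom = rec$id, start = p$start - 1L, end = p$end, name = p$region)
    } else {
      tibble(chrom = rec$id,
             start = c(p$start - 1L, 0L),
             end = c(n, p$end - n),
             name = p$region)
    }
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
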