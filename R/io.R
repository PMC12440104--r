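#' @keywords internal
pgin_log <- function(...) {
  message("[pgin] ", ...)
}

# canonical variant-table schema: name -> type
.VARIANT_COLUMNS <- c(
  sample_id = "character", chrom = "character", pos = "integer",
  ref = "character", alt = "character", gene = "character",
  classification = "character", variant_type = "character",
  dp = "numeric", gq = "numeric", qd = "numeric", mq = "numeric",
  read_pos_rank_sum = "numeric", mq_rank_sum = "numeric",
  fs = "numeric", qual = "numeric", max_af = "numeric",
  polyphen = "character", sift = "character", clinvar_sig = "character",
  alt_count = "numeric", ref_count = "numeric",
  context5 = "character", context3 = "character",
  rna_editing_site = "logical", low_complexity = "logical",
  common_variant = "logical"
)

.REQUIRED_VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt",
                               "gene")

.CLASSIFICATIONS <- c("missense", "nonsense", "nonstop", "frameshift",
                      "splice", "silent", "other")

.as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

.coerce_numeric_col <- function(x, col) {
  if (is.numeric(x)) return(x)
  v <- trimws(as.character(x))
  v[v %in% c("", "NA", "na", ".", "nan")] <- NA
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' at data line %d",
                 v[bad[1]], col, bad[1]))
  }
  out
}

.normalize_categorical <- function(x, levels) {
  v <- tolower(trimws(as.character(x)))
  v[v %in% c("", "na", ".")] <- NA
  v[!is.na(v) & !v %in% levels] <- "other"
  v
}

#' Read an annotated somatic variant table
#'
#' Reads either a MAF-like tab-separated table (one row per variant per
#' sample, canonical column names, adaptable via \code{column_map}) or a
#' minimal single-sample VCF whose annotations live in INFO keys. Missing
#' annotation cells become explicit \code{NA}s; they are never silently
#' coerced to passing values.
#'
#' Canonical columns: sample_id, chrom, pos, ref, alt, gene,
#' classification, variant_type, dp, gq, qd, mq, read_pos_rank_sum,
#' mq_rank_sum, fs, qual, max_af, polyphen, sift, clinvar_sig, alt_count,
#' ref_count, context5, context3, rna_editing_site, low_complexity,
#' common_variant. Only the first six are required; absent columns are
#' filled with \code{NA}.
#'
#' @param path path to the input file.
#' @param dialect one of \code{"maf_like"} or \code{"minimal_vcf"}.
#' @param column_map optional named character vector mapping canonical
#'   column names to the header names used in the file.
#' @return A data.frame of variant records in canonical columns.
#' @export
read_variant_table <- function(path, dialect = c("maf_like", "minimal_vcf"),
                               column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path)
  if (dialect == "minimal_vcf") {
    return(.read_minimal_vcf(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  missing_req <- setdiff(.REQUIRED_VARIANT_COLUMNS, names(df))
  if (length(missing_req)) {
    stop("variant table is missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  as_variant_table(df)
}

#' Coerce a raw data.frame to the canonical variant-table layout
#'
#' @param df data.frame holding at least the required identifier columns.
#' @return Canonicalized data.frame (all schema columns, typed).
#' @export
as_variant_table <- function(df) {
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (col in names(.VARIANT_COLUMNS)) {
    type <- .VARIANT_COLUMNS[[col]]
    if (!col %in% names(df)) {
      out[[col]] <- switch(type,
        character = rep(NA_character_, nrow(df)),
        numeric = rep(NA_real_, nrow(df)),
        integer = rep(NA_integer_, nrow(df)),
        logical = rep(NA, nrow(df)))
      next
    }
    x <- df[[col]]
    out[[col]] <- switch(type,
      character = { v <- trimws(as.character(x)); v[v %in% c("", ".")] <- NA; v },
      numeric = .coerce_numeric_col(x, col),
      integer = as.integer(.coerce_numeric_col(x, col)),
      logical = .as_logical_col(x))
  }
  out$classification <- .normalize_categorical(out$classification,
                                               .CLASSIFICATIONS)
  out$polyphen <- .normalize_categorical(
    out$polyphen, c("damaging", "possibly_damaging", "benign"))
  out$sift <- .normalize_categorical(out$sift, c("deleterious", "tolerated"))
  cv <- tolower(trimws(as.character(out$clinvar_sig)))
  cv[cv %in% c("", "na", ".")] <- NA
  out$clinvar_sig <- cv
  for (fl in c("rna_editing_site", "low_complexity", "common_variant")) {
    out[[fl]][is.na(out[[fl]])] <- FALSE
  }
  # derive variant_type where absent
  need <- is.na(out$variant_type) & !is.na(out$ref) & !is.na(out$alt)
  out$variant_type[need] <- ifelse(
    nchar(out$ref[need]) == 1 & nchar(out$alt[need]) == 1, "SNV",
    ifelse(nchar(out$alt[need]) > nchar(out$ref[need]), "INS", "DEL"))
  out$variant_type <- toupper(out$variant_type)
  if (any(!is.na(out$pos) & out$pos < 1)) stop("positions must be >= 1")
  bad_af <- !is.na(out$max_af) & (out$max_af < 0 | out$max_af > 1)
  if (any(bad_af)) stop("max_af outside [0,1] at row ", which(bad_af)[1])
  rownames(out) <- NULL
  out
}

.read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("minimal VCF lacks a #CHROM header line")
  body <- lines[seq_along(lines) > hdr[1] & !grepl("^#", lines)]
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  sample_id <- if (length(cols) >= 10) cols[10] else
    sub("\\.vcf$", "", basename(path))
  if (!length(body)) {
    return(as_variant_table(data.frame(sample_id = character(),
                                       chrom = character(), pos = integer(),
                                       ref = character(), alt = character(),
                                       gene = character())))
  }
  parts <- strsplit(body, "\t")
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0("^(;)?", key, "="), "", sub("^;", "", m))
  }
  rows <- lapply(parts, function(p) {
    info <- if (length(p) >= 8) p[8] else ""
    keys <- c(gene = "GENE", classification = "CLASS", dp = "DP", gq = "GQ",
              qd = "QD", mq = "MQ", read_pos_rank_sum = "ReadPosRankSum",
              mq_rank_sum = "MQRankSum", fs = "FS", max_af = "MAX_AF",
              polyphen = "PolyPhen", sift = "SIFT", clinvar_sig = "CLIN_SIG",
              alt_count = "AC_ALT", ref_count = "AC_REF",
              context5 = "CTX5", context3 = "CTX3",
              rna_editing_site = "RNA_EDIT", low_complexity = "LOWCOMPLEX",
              common_variant = "COMMON")
    vals <- vapply(keys, function(k) info_get(info, k), character(1))
    c(sample_id = sample_id, chrom = p[1], pos = p[2], ref = p[4],
      alt = p[5], qual = p[6], vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  as_variant_table(df)
}

#' Write a variant table to TSV
#'
#' Emits the canonical columns; \code{NA} cells are written as empty
#' strings so that a round trip through \code{\link{read_variant_table}}
#' preserves both values and missingness.
#'
#' @param variants canonical variant data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a bedtools-genomecov style coverage histogram
#'
#' Accepts either the default 5-column genomecov histogram
#' (feature, depth, count, feature_size, fraction) or a minimal 2-column
#' (depth, count) dialect. When genome-wide rows (feature "genome") are
#' present they are preferred over per-contig rows; otherwise per-contig
#' counts at the same depth are summed. Duplicate depth rows are summed.
#'
#' @param path path to the TSV (no header).
#' @param sample_id identifier to attach; defaults to the file stem.
#' @return A list of class \code{"coverage_profile"} with elements
#'   \code{sample_id} and \code{depth_hist} (named integer vector,
#'   names = depth).
#' @export
read_coverage <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt|bed)$", "", basename(path))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 3) {
    names(df)[1:3] <- c("feature", "depth", "count")
    if (any(df$feature == "genome")) df <- df[df$feature == "genome", ]
  } else if (ncol(df) == 2) {
    names(df) <- c("depth", "count")
  } else {
    stop("unrecognized coverage dialect: expected 2 or >=3 columns")
  }
  df$depth <- .coerce_numeric_col(df$depth, "depth")
  df$count <- .coerce_numeric_col(df$count, "count")
  if (any(df$depth < 0) || any(df$count < 0)) {
    stop("coverage depths and counts must be non-negative")
  }
  coverage_profile(sample_id,
                   tapply(df$count, df$depth, sum))
}

#' Construct a coverage profile from a depth histogram
#'
#' @param sample_id sample identifier.
#' @param depth_hist named numeric vector, names = integer depth,
#'   values = number of genome positions at exactly that depth.
#' @return Object of class \code{"coverage_profile"}.
#' @export
coverage_profile <- function(sample_id, depth_hist) {
  depth_hist <- stats::setNames(as.numeric(depth_hist), names(depth_hist))
  depth_hist <- depth_hist[order(as.numeric(names(depth_hist)))]
  if (any(depth_hist < 0)) stop("negative counts in depth histogram")
  structure(list(sample_id = sample_id,
                 depth_hist = depth_hist),
            class = "coverage_profile")
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column holds gene symbols; remaining columns are samples.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#' @param expression genes x samples numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' CSV with columns sample_id, ga_weeks, pe, mvm, sga, fetal_sex,
#' maternal_age (extra columns are kept).
#'
#' @param path CSV path.
#' @return data.frame with typed columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "ga_weeks", "pe")
  missing_req <- setdiff(req, names(df))
  if (length(missing_req)) {
    stop("metadata is missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  for (fl in intersect(c("pe", "mvm", "sga"), names(df))) {
    df[[fl]] <- .as_logical_col(df[[fl]])
  }
  df$ga_weeks <- .coerce_numeric_col(df$ga_weeks, "ga_weeks")
  if ("maternal_age" %in% names(df)) {
    df$maternal_age <- .coerce_numeric_col(df$maternal_age, "maternal_age")
  }
  df
}

#' Read hypoxia gene signatures from a two-column TSV
#'
#' Columns: signature name, gene symbol (header optional, detected).
#'
#' @param path TSV path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_signatures <- function(path) {
  if (!file.exists(path)) stop("gene signature file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("signature", tolower(first))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("signature", "gene")
  sigs <- split(df$gene, df$signature)
  lapply(sigs, unique)
}
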