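#' Build fixed-length meter feature vectors for classification
#'
#' Takes the first 30 s of one meter trace per recording — 300 values on the
#' 100 ms grid — as a numeric feature vector. Recordings longer than the
#' window are truncated; shorter ones are right-padded with 0 U (silence).
#' The class label is the recording's group.
#'
#' @param records list of per-recording entries; each needs the requested
#'   meter trace (`$vu` or `$ppm`, a `meter_trace`) and `$metadata$group`
#'   (or `$group`).
#' @param meter `"VU"` or `"PPM"`.
#' @param window_s analysis window in seconds (default 30).
#' @return A `feature_dataset`: list with `x` (instances x attributes numeric
#'   matrix), `class` (factor with levels `M`, `C`), `meter`,
#'   `attribute_names`.
#' @export
build_feature_vectors <- function(records, meter = c("VU", "PPM"),
                                  window_s = 30) {
  meter <- match.arg(meter)
  if (!length(records)) stop("empty cohort", call. = FALSE)
  n_attr <- as.integer(round(window_s * 10))
  rows <- lapply(records, function(rec) {
    tr <- if (meter == "VU") rec$vu else rec$ppm
    if (is.null(tr)) stop("record lacks a ", meter, " trace", call. = FALSE)
    v <- tr$values
    if (!length(v)) stop("record has an empty trace", call. = FALSE)
    length(v) <- n_attr            # truncate or NA-extend
    v[is.na(v)] <- 0               # silence padding
    v
  })
  labs <- vapply(records, function(rec) {
    g <- rec$metadata$group %||% rec$group
    if (is.null(g)) stop("record lacks a group label", call. = FALSE)
    g
  }, character(1))
  feature_dataset(do.call(rbind, rows), factor(labs, levels = c("M", "C")),
                  meter = meter)
}

#' Construct a feature dataset
#'
#' @param x numeric matrix, instances in rows; no missing values.
#' @param class factor of class labels with levels `M`, `C` (one per row).
#' @param meter meter kind the attributes came from (`"VU"`, `"PPM"` or
#'   other).
#' @param attribute_names optional attribute names (default `a1..ap`).
#' @return A `feature_dataset`.
#' @export
feature_dataset <- function(x, class, meter = "VU", attribute_names = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(class))
    stop("class length must match instance count", call. = FALSE)
  if (anyNA(x)) stop("missing attribute values not allowed", call. = FALSE)
  if (!is.factor(class)) class <- factor(class, levels = c("M", "C"))
  attribute_names <- attribute_names %||% paste0("a", seq_len(ncol(x)))
  colnames(x) <- attribute_names
  structure(list(x = x, class = class, meter = meter,
                 attribute_names = attribute_names),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset (%s): %d instances x %d attributes; %s>\n",
              x$meter, nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", levels(x$class), table(x$class)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a feature dataset as an ARFF file
#'
#' Standard ARFF: an `@relation` line, one numeric `@attribute` per feature,
#' one nominal class attribute, then `@data` rows. Numeric values are written
#' with 17 significant digits so doubles round-trip exactly.
#'
#' @param d a `feature_dataset`.
#' @param path output path.
#' @param relation relation name.
#' @return `path`, invisibly.
#' @seealso [read_arff()]
#' @export
write_arff <- function(d, path, relation = paste0("cry_", tolower(d$meter))) {
  stopifnot(inherits(d, "feature_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@relation %s", relation), con)
  writeLines(sprintf("@attribute %s numeric", d$attribute_names), con)
  writeLines(sprintf("@attribute class {%s}",
                     paste(levels(d$class), collapse = ",")), con)
  writeLines("@data", con)
  if (nrow(d$x)) {
    vals <- apply(d$x, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(paste(vals, as.character(d$class), sep = ","), con)
  }
  invisible(path)
}

#' Read an ARFF file written for the cry classification study
#'
#' Parses numeric attributes plus one trailing nominal class attribute.
#' Malformed input raises an error naming the offending line number.
#'
#' @param path ARFF file path.
#' @return A `feature_dataset`.
#' @export
read_arff <- function(path) {
  lines <- readLines(path)
  trimmed <- trimws(lines)
  parse_err <- function(i, msg)
    stop(sprintf("ARFF parse error at line %d: %s", i, msg), call. = FALSE)

  attr_names <- character(0)
  attr_kinds <- character(0)
  class_levels <- NULL
  relation <- ""
  data_start <- NA_integer_
  for (i in seq_along(trimmed)) {
    ln <- trimmed[i]
    if (ln == "" || startsWith(ln, "%")) next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) {
      relation <- trimws(sub("^@\\S+", "", ln))
      next
    }
    if (startsWith(low, "@attribute")) {
      m <- regmatches(ln, regexec(
        "^@[aA][tT][tT][rR][iI][bB][uU][tT][eE]\\s+(\\S+)\\s+(.+)$", ln))[[1]]
      if (length(m) != 3) parse_err(i, "malformed @attribute declaration")
      typ <- trimws(m[3])
      if (grepl("^\\{.*\\}$", typ)) {
        class_levels <- trimws(strsplit(gsub("[{}]", "", typ), ",")[[1]])
        attr_names <- c(attr_names, m[2])
        attr_kinds <- c(attr_kinds, "nominal")
      } else if (tolower(typ) %in% c("numeric", "real", "integer")) {
        attr_names <- c(attr_names, m[2])
        attr_kinds <- c(attr_kinds, "numeric")
      } else parse_err(i, paste("unsupported attribute type:", typ))
    } else if (startsWith(low, "@data")) {
      data_start <- i + 1L
      break
    } else parse_err(i, paste("unexpected content:", ln))
  }
  if (is.na(data_start)) parse_err(length(lines), "missing @data section")
  if (!length(attr_kinds) || attr_kinds[length(attr_kinds)] != "nominal")
    parse_err(data_start - 1L, "last attribute must be the nominal class")
  if (any(attr_kinds[-length(attr_kinds)] != "numeric"))
    parse_err(data_start - 1L, "non-class attributes must be numeric")

  p <- length(attr_names) - 1L
  rows <- list(); labs <- character(0)
  for (i in seq(data_start, length.out = max(0, length(trimmed) - data_start + 1))) {
    ln <- trimmed[i]
    if (ln == "" || startsWith(ln, "%")) next
    parts <- trimws(strsplit(ln, ",")[[1]])
    if (length(parts) != p + 1L)
      parse_err(i, sprintf("expected %d fields, found %d", p + 1L,
                           length(parts)))
    v <- suppressWarnings(as.numeric(parts[seq_len(p)]))
    if (anyNA(v)) parse_err(i, "non-numeric attribute value")
    if (!parts[p + 1L] %in% class_levels)
      parse_err(i, paste("unknown class label:", parts[p + 1L]))
    rows[[length(rows) + 1]] <- v
    labs <- c(labs, parts[p + 1L])
  }
  x <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = p)
  meter <- if (grepl("ppm", tolower(relation))) "PPM" else "VU"
  feature_dataset(x, factor(labs, levels = class_levels),
                  meter = meter, attribute_names = attr_names[seq_len(p)])
}
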