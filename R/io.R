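#' Read a samples x features matrix from delimited text
#'
#' Expects one header row of feature ids and one leading column of sample
#' ids; the delimiter (tab or comma) is auto-detected from the header line.
#' Ragged rows, duplicate ids, and non-numeric cells are rejected with the
#' offending location; empty fields are missing values and are rejected
#' unless `impute_missing = TRUE` (column-mean imputation).
#'
#' @param path File path.
#' @param impute_missing Replace missing cells by their column mean
#'   (default `FALSE`: missing cells are an error).
#' @return Numeric matrix with sample ids as row names and feature ids as
#'   column names.
#' @export
read_matrix <- function(path, impute_missing = FALSE) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  nfields <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nfields)) != 1) {
    bad <- which(nfields != nfields[1])[1]
    stop("parse error: ragged row ", bad, " (", nfields[bad],
         " fields, expected ", nfields[1], ")")
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = NULL,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  sample_ids <- df[[1]]
  if (anyDuplicated(sample_ids)) {
    stop("parse error: duplicate sample id '",
         sample_ids[duplicated(sample_ids)][1], "'")
  }
  feature_ids <- colnames(df)[-1]
  if (anyDuplicated(feature_ids)) {
    stop("parse error: duplicate feature id '",
         feature_ids[duplicated(feature_ids)][1], "'")
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells == ""] <- NA
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells),
                                 ncol(cells)))
  bad <- is.na(num) & !is.na(cells)
  if (any(bad)) {
    loc <- which(bad, arr.ind = TRUE)[1, ]
    stop("parse error: non-numeric value '", cells[bad][1], "' at row ",
         loc[1], ", column '", feature_ids[loc[2]], "'")
  }
  if (any(is.na(num))) {
    if (!impute_missing) {
      loc <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop("parse error: missing value at row ", loc[1], ", column '",
           feature_ids[loc[2]], "' (set impute_missing = TRUE to impute)")
    }
    for (j in seq_len(ncol(num))) {
      miss <- is.na(num[, j])
      if (any(miss)) num[miss, j] <- mean(num[!miss, j])
    }
  }
  dimnames(num) <- list(sample_ids, feature_ids)
  num
}

#' Write a samples x features matrix as delimited text
#'
#' One header row of feature ids, one leading `sample_id` column;
#' round-trips through [read_matrix()].
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output file path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @export
write_matrix <- function(x, path, sep = "\t") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binary labels aligned to a sample ordering
#'
#' Two-column delimited file (sample id, label in `{0,1}`; an optional
#' header row is detected). The labels are reordered to `sample_ids`;
#' missing or unknown samples are an explicit error naming the ids.
#'
#' @param path File path.
#' @param sample_ids Character vector defining the output order.
#' @return Integer vector of labels named by `sample_ids`.
#' @export
read_labels <- function(path, sample_ids) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  first <- strsplit(header, sep, fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 && !first[2] %in% c("0", "1")
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) != 2) stop("parse error: labels file must have two columns")
  ids <- df[[1]]
  vals <- df[[2]]
  if (!all(vals %in% c("0", "1"))) {
    stop("parse error: non-binary label value '",
         vals[!vals %in% c("0", "1")][1], "'")
  }
  missing <- setdiff(sample_ids, ids)
  if (length(missing) > 0) {
    stop("parse error: labels missing for sample(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(ids, sample_ids)
  if (length(extra) > 0) {
    stop("parse error: labels for unknown sample(s): ",
         paste(extra, collapse = ", "))
  }
  stats::setNames(as.integer(vals), ids)[sample_ids]
}

#' Write binary labels
#'
#' @param labels Binary vector named by sample id.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_labels <- function(labels, path, sep = "\t") {
  stopifnot(!is.null(names(labels)))
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted `glm_model` to flat JSON
#'
#' @param model A `glm_model`.
#' @param path Output file path.
#' @export
write_glm_model <- function(model, path) {
  stopifnot(inherits(model, "glm_model"))
  doc <- list(
    family = model$family,
    penalty = model$penalty,
    penalty_strength = model$penalty_strength,
    feature_ids = model$feature_ids,
    weights = unname(model$weights),
    intercept = model$intercept,
    center = unname(model$center),
    scale = unname(model$scale)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a `glm_model` serialized by [write_glm_model()]
#'
#' @param path File path.
#' @return A `glm_model`.
#' @export
read_glm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    family = doc$family,
    weights = stats::setNames(as.numeric(doc$weights), doc$feature_ids),
    intercept = as.numeric(doc$intercept),
    penalty = doc$penalty,
    penalty_strength = as.numeric(doc$penalty_strength),
    feature_ids = doc$feature_ids,
    center = stats::setNames(as.numeric(doc$center), doc$feature_ids),
    scale = stats::setNames(as.numeric(doc$scale), doc$feature_ids)
  ), class = "glm_model")
}

#' Write a JSON run manifest
#'
#' Records the command, parameters, seed, input-file MD5 digests, package
#' version, and timestamp, so a run can be reproduced exactly.
#'
#' @param path Output file path.
#' @param command Short name of the analysis step.
#' @param parameters Named list of run parameters.
#' @param seed Integer seed used for the run.
#' @param inputs Character vector of input file paths (digested).
#' @export
write_manifest <- function(path, command, parameters, seed,
                           inputs = character(0)) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  doc <- list(
    command = command,
    parameters = parameters,
    seed = seed,
    input_md5 = digests,
    package_version = as.character(utils::packageVersion("chemoclass")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
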