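# Readers and writers: GMT gene-set collections, RNK ranked lists, GCT
# expression matrices, DEG-signature and pairing TSVs. All writers accept
# `#`-prefixed provenance headers that every reader ignores.

provenance_lines <- function(provenance) {
  if (is.null(provenance)) {
    return(character())
  }
  c(
    sprintf("# sigconnect %s", as.character(packageVersion("sigconnect"))),
    vapply(
      names(provenance),
      function(k) sprintf("# %s: %s", k, paste(provenance[[k]], collapse = " ")),
      character(1)
    )
  )
}

read_body_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  structure(lines[keep], line_numbers = which(keep))
}

#' Read a GMT gene-set collection
#'
#' One gene set per tab-separated line: name, description, then members.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors, with the per-set descriptions
#'   in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- read_body_lines(path)
  nums <- attr(lines, "line_numbers")
  if (length(lines) == 0) abort(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed GMT line %d in %s: expected at least 3 tab-separated fields.",
      nums[bad[1]], path
    ))
  }
  sets <- list()
  descriptions <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf(
        "Duplicate members in gene set `%s` (line %d) deduplicated.",
        f[1], nums[i]
      ))
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    descriptions[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' @rdname read_gmt
#' @param collection Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(is.list(collection), length(collection) > 0, !is.null(names(collection)))
  descriptions <- descriptions %||%
    attr(collection, "descriptions") %||%
    setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a RNK ranked-list file
#'
#' Two tab-separated columns, gene and signed score; `#` comment lines are
#' ignored. The genes are re-ranked on read via [build_ranked_list()], so
#' a written ranked list round-trips identically.
#'
#' @param path Path to a RNK file.
#' @return [read_rnk()] returns a `ranked_list`.
#' @export
read_rnk <- function(path) {
  lines <- read_body_lines(path)
  nums <- attr(lines, "line_numbers")
  if (length(lines) == 0) abort(sprintf("RNK file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed RNK line %d in %s: expected `gene<TAB>score`.",
      nums[bad[1]], path
    ))
  }
  genes <- vapply(fields, `[`, character(1), 1)
  scores <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  if (anyNA(scores)) {
    abort(sprintf(
      "Non-numeric score on RNK line %d in %s.",
      nums[which(is.na(scores))[1]], path
    ))
  }
  build_ranked_list(setNames(scores, genes))
}

#' @rdname read_rnk
#' @param ranked A `ranked_list`.
#' @param provenance Optional named list written as `# key: value` header
#'   lines.
#' @export
write_rnk <- function(ranked, path, provenance = NULL) {
  validate_ranked_list(ranked)
  lines <- c(
    provenance_lines(provenance),
    sprintf("%s\t%.17g", ranked$gene, ranked$score)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a DEG-signature TSV
#'
#' Two tab-separated columns `gene`, `direction` with direction `up` or
#' `down`; `#` comments and an optional header row are ignored.
#'
#' @param path Path to the TSV.
#' @param study_name Signature label; defaults to the file name.
#' @return [read_deg_signature()] returns a `deg_signature`.
#' @export
read_deg_signature <- function(path, study_name = NULL) {
  lines <- read_body_lines(path)
  nums <- attr(lines, "line_numbers")
  if (length(lines) == 0) abort(sprintf("Signature file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1]), "gene")) {
    fields <- fields[-1]
    nums <- nums[-1]
  }
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed signature line %d in %s: expected `gene<TAB>direction`.",
      nums[bad[1]], path
    ))
  }
  gene <- vapply(fields, `[`, character(1), 1)
  direction <- tolower(vapply(fields, `[`, character(1), 2))
  bad_dir <- which(!direction %in% c("up", "down"))
  if (length(bad_dir) > 0) {
    abort(sprintf(
      "Invalid direction `%s` on line %d in %s (expected `up` or `down`).",
      direction[bad_dir[1]], nums[bad_dir[1]], path
    ))
  }
  load_signature(
    gene[direction == "up"], gene[direction == "down"],
    study_name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' @rdname read_deg_signature
#' @param signature A `deg_signature`.
#' @param provenance Optional named list written as `# key: value` header
#'   lines.
#' @export
write_deg_signature <- function(signature, path, provenance = NULL) {
  stopifnot(is_deg_signature(signature))
  df <- tidy(signature)
  lines <- c(
    provenance_lines(provenance),
    "gene\tdirection",
    sprintf("%s\t%s", df$gene, df$direction)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a GCT 1.2 expression matrix
#'
#' The GCT 1.2 layout: `#1.2`, a dimensions line, then a header row
#' (`Name`, `Description`, sample ids) and one row per feature.
#'
#' @param path Path to the GCT file.
#' @return [read_gct()] returns a numeric matrix with feature rownames.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !grepl("^#1\\.2", lines[1])) {
    abort(sprintf("Not a GCT 1.2 file: %s", path))
  }
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:2)]
  if (length(samples) != dims[2]) {
    abort(sprintf("GCT header declares %d samples but has %d.", dims[2], length(samples)))
  }
  body <- strsplit(lines[3 + seq_len(dims[1])], "\t", fixed = TRUE)
  features <- vapply(body, `[`, character(1), 1)
  values <- t(vapply(
    body,
    function(f) as.numeric(f[-(1:2)]),
    numeric(length(samples))
  ))
  if (anyNA(values)) abort(sprintf("Non-numeric expression value in %s.", path))
  dimnames(values) <- list(features, samples)
  values
}

#' @rdname read_gct
#' @param exprs Numeric matrix with feature rownames and sample colnames,
#'   or a [paired_expression()].
#' @export
write_gct <- function(exprs, path) {
  if (inherits(exprs, "paired_expression")) exprs <- exprs$exprs
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)), !is.null(colnames(exprs)))
  lines <- c(
    "#1.2",
    sprintf("%d\t%d", nrow(exprs), ncol(exprs)),
    paste(c("Name", "Description", colnames(exprs)), collapse = "\t"),
    vapply(seq_len(nrow(exprs)), function(i) {
      paste(c(rownames(exprs)[i], "na", sprintf("%.17g", exprs[i, ])),
        collapse = "\t"
      )
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a sample-pairing TSV
#'
#' Three tab-separated columns: `patient`, `lesional`, `nonlesional`.
#'
#' @param path Path to the TSV.
#' @return [read_pairing()] returns a tibble.
#' @export
read_pairing <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- as_tibble(read.delim(path, comment.char = "#", colClasses = "character"))
  req <- c("patient", "lesional", "nonlesional")
  if (!all(req %in% names(df))) {
    abort("Pairing file needs columns `patient`, `lesional`, `nonlesional`.")
  }
  df[req]
}

#' @rdname read_pairing
#' @param pairing Data frame with columns `patient`, `lesional`,
#'   `nonlesional`.
#' @param provenance Optional named list written as `# key: value` header
#'   lines.
#' @export
write_pairing <- function(pairing, path, provenance = NULL) {
  stopifnot(all(c("patient", "lesional", "nonlesional") %in% names(pairing)))
  lines <- c(
    provenance_lines(provenance),
    "patient\tlesional\tnonlesional",
    sprintf("%s\t%s\t%s", pairing$patient, pairing$lesional, pairing$nonlesional)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probeset-to-gene platform map
#'
#' Two tab-separated columns: `probeset_id`, `gene_id`.
#'
#' @param path Path to the TSV.
#' @param platform_name Optional label stored as an attribute.
#' @return Tibble with columns `probeset_id`, `gene_id`.
#' @export
read_platform_map <- function(path, platform_name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- as_tibble(read.delim(path, comment.char = "#", colClasses = "character"))
  if (!all(c("probeset_id", "gene_id") %in% names(df))) {
    abort("Platform map needs columns `probeset_id`, `gene_id`.")
  }
  if (anyDuplicated(df$probeset_id)) {
    abort("`probeset_id` values must be unique within a platform map.")
  }
  out <- df[c("probeset_id", "gene_id")]
  attr(out, "platform_name") <- platform_name %||% basename(path)
  out
}

# Write a data frame as TSV with provenance header lines.
write_tsv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(provenance), con)
  write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}
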