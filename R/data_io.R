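#' Read a gene-expression matrix from delimited text
#'
#' The expected layout is samples in rows: a header of gene identifiers and
#' a first column of sample identifiers. Files with genes in rows are read
#' with `orientation = "genes-in-rows"` and transposed on load. Tab- and
#' comma-separated files are both accepted (the separator is sniffed).
#'
#' Values are assumed to be log-normalized upstream; set
#' `log2_transform = TRUE` to apply `log2(x + 1)` on load (default off).
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples-in-rows"` (default) or `"genes-in-rows"`.
#' @param log2_transform Apply `log2(x + 1)` to all values after reading.
#' @return A numeric matrix (samples x genes) with unique `rownames`
#'   (sample ids) and `colnames` (gene ids); no missing values.
#' @export
read_expression <- function(path,
                            orientation = c("samples-in-rows", "genes-in-rows"),
                            log2_transform = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          data.table = FALSE, na.strings = c("NA", ""))
  if (ncol(dt) < 2L || nrow(dt) < 1L) {
    stop("expression file must have an id column plus at least one value column")
  }
  ids <- as.character(dt[[1L]])
  m <- suppressWarnings(
    vapply(dt[-1L], function(col) as.numeric(col), numeric(nrow(dt)))
  )
  m <- matrix(m, nrow = nrow(dt),
              dimnames = list(ids, colnames(dt)[-1L]))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "missing or non-numeric expression value at row '%s', column '%s'",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  if (orientation == "genes-in-rows") m <- t(m)
  if (log2_transform) m <- log2(m + 1)
  validate_expression(m)
  m
}

validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (nrow(m) < 2L) stop("expression matrix needs at least 2 samples")
  if (ncol(m) < 1L) stop("expression matrix needs at least 1 gene")
  if (anyNA(m) || any(!is.finite(m))) stop("expression matrix contains non-finite values")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("duplicate or missing sample ids in expression matrix")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate or missing gene ids in expression matrix")
  invisible(m)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles exactly.
#'
#' @param m Numeric samples x genes matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  df <- data.frame(sample_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(m))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read survival outcomes from delimited text
#'
#' Expects three columns: sample id, follow-up time, event indicator
#' (1 = event observed, 0 = censored). Column names are free; order is
#' positional.
#'
#' @param path Path to a delimited text file.
#' @return A `data.frame` with columns `id` (character), `time`
#'   (nonnegative numeric), `event` (integer 0/1).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "auto", data.table = FALSE),
    error = function(e) stop("no records in survival file: ", path))
  if (nrow(dt) == 0L) stop("no records in survival file: ", path)
  if (ncol(dt) < 3L) stop("survival file must have columns (id, time, event)")
  out <- data.frame(id = as.character(dt[[1L]]),
                    time = suppressWarnings(as.numeric(dt[[2L]])),
                    event = suppressWarnings(as.numeric(dt[[3L]])),
                    stringsAsFactors = FALSE)
  validate_survival(out)
  out$event <- as.integer(out$event)
  out
}

validate_survival <- function(s) {
  stopifnot(is.data.frame(s), all(c("id", "time", "event") %in% names(s)))
  if (nrow(s) == 0L) stop("no records in survival table")
  if (anyDuplicated(s$id)) stop("duplicate sample ids in survival table")
  if (anyNA(s$time) || any(!is.finite(s$time))) stop("non-numeric survival time")
  if (any(s$time < 0)) stop("negative survival time for sample ", s$id[which(s$time < 0)[1L]])
  if (anyNA(s$event) || !all(s$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1")
  invisible(s)
}

#' Write survival outcomes as tab-separated text
#' @param s Survival `data.frame` (id, time, event).
#' @param path Output path.
#' @export
write_survival <- function(s, path) {
  validate_survival(s)
  df <- data.frame(id = s$id, time = sprintf("%.17g", s$time),
                   event = as.integer(s$event))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Assemble an aligned cohort from expression and survival
#'
#' Samples are intersected by id and ordered identically in both parts.
#'
#' @param expression Samples x genes numeric matrix.
#' @param survival Survival `data.frame` (id, time, event).
#' @return A `cohort_dataset`: list with elements `expression`, `survival`.
#' @export
cohort_dataset <- function(expression, survival) {
  validate_expression(expression)
  validate_survival(survival)
  common <- intersect(rownames(expression), survival$id)
  if (length(common) < 2L) stop("fewer than 2 samples shared between expression and survival")
  expression <- expression[common, , drop = FALSE]
  survival <- survival[match(common, survival$id), , drop = FALSE]
  rownames(survival) <- NULL
  structure(list(expression = expression, survival = survival),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d samples x %d genes, %d events (%.1f%% censored)\n",
              nrow(x$expression), ncol(x$expression), sum(x$survival$event),
              100 * mean(x$survival$event == 0)))
  invisible(x)
}

#' Read a GMT pathway file
#'
#' One pathway per line, tab-separated: name, description, then member gene
#' identifiers (at least one).
#'
#' @param path Path to a GMT file.
#' @return A `pathway_collection`: list with `pathway_names`, `members`
#'   (list of character vectors, file order preserved), `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d has %d fields; expected name, description, members",
                 which(nf < 3L)[1L], nf[which(nf < 3L)[1L]]))
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop("duplicate pathway names in GMT file")
  pathway_collection(
    pathway_names = nm,
    members = lapply(fields, function(f) unique(f[-(1:2)])),
    descriptions = vapply(fields, `[[`, character(1L), 2L))
}

#' Construct a pathway collection
#' @param pathway_names Character vector of q pathway names.
#' @param members List of q character vectors of member gene ids.
#' @param descriptions Optional character vector of q descriptions.
#' @return A `pathway_collection` object.
#' @export
pathway_collection <- function(pathway_names, members,
                               descriptions = rep("", length(pathway_names))) {
  stopifnot(length(pathway_names) >= 1L,
            length(members) == length(pathway_names),
            all(lengths(members) >= 1L))
  if (anyDuplicated(pathway_names)) stop("duplicate pathway names")
  structure(list(pathway_names = as.character(pathway_names),
                 members = lapply(members, as.character),
                 descriptions = as.character(descriptions)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, member sizes %d-%d\n",
              length(x$pathway_names), min(lengths(x$members)),
              max(lengths(x$members))))
  invisible(x)
}

#' Write a pathway collection as GMT
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  lines <- mapply(function(nm, d, mem) paste(c(nm, d, mem), collapse = "\t"),
                  pathways$pathway_names, pathways$descriptions,
                  pathways$members)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Build the binary pathway-by-gene biadjacency mask
#'
#' Row i, column j is 1 iff gene j belongs to pathway i. The mask gates the
#' first (sparse) layer of the network: a connection exists only where the
#' mask is 1. Pathway membership is matched by exact, case-sensitive id.
#' Pathways with no gene present in `gene_ids` are removed. Genes belonging
#' to no retained pathway are, by default, dropped from the model input
#' (`unmapped = "drop"`); `unmapped = "catchall"` instead adds one extra
#' pseudo-pathway row connecting all such genes.
#'
#' @param pathways A `pathway_collection`.
#' @param gene_ids Character vector of gene ids from the expression matrix.
#' @param unmapped Policy for genes in no pathway: `"drop"` or `"catchall"`.
#' @return A `pathway_mask`: list with `matrix` (q x p binary, dimnames set),
#'   `pathway_names`, `gene_ids` (retained genes, expression order),
#'   `dropped_genes`.
#' @export
build_pathway_mask <- function(pathways, gene_ids,
                               unmapped = c("drop", "catchall")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(pathways, "pathway_collection"), length(gene_ids) >= 1L)
  members <- lapply(pathways$members, intersect, y = gene_ids)
  keep <- lengths(members) > 0L
  if (!any(keep)) stop("no gene-pathway overlap")
  members <- members[keep]
  pnames <- pathways$pathway_names[keep]
  mapped <- unique(unlist(members))
  dropped <- setdiff(gene_ids, mapped)
  if (unmapped == "catchall" && length(dropped) > 0L) {
    members <- c(members, list(dropped))
    pnames <- c(pnames, "UNMAPPED")
    mapped <- gene_ids
    dropped <- character(0L)
  }
  genes <- gene_ids[gene_ids %in% mapped]  # keep expression column order
  A <- matrix(0, nrow = length(members), ncol = length(genes),
              dimnames = list(pnames, genes))
  for (i in seq_along(members)) {
    A[i, match(members[[i]], genes)] <- 1
  }
  if (length(dropped) > 0L) {
    message(length(dropped), " gene(s) matched no pathway and were dropped from the model input")
  }
  structure(list(matrix = A, pathway_names = pnames, gene_ids = genes,
                 dropped_genes = dropped),
            class = "pathway_mask")
}

#' @export
print.pathway_mask <- function(x, ...) {
  cat(sprintf("pathway_mask: %d pathways x %d genes, density %.3f, %d gene(s) dropped\n",
              nrow(x$matrix), ncol(x$matrix), mean(x$matrix), length(x$dropped_genes)))
  invisible(x)
}
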