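#' Read a drug table
#'
#' Expects a TSV with header columns \code{drug_id}, \code{name},
#' \code{targets} and \code{atc_codes}; the latter two are
#' semicolon-joined multi-value cells (possibly empty). Records are
#' returned sorted by \code{drug_id}, so permuting input rows yields an
#' identical collection.
#'
#' @param path path to the TSV file.
#' @return a \code{DrugSet}.
#' @details Malformed ATC codes are dropped with a per-row warning;
#'   duplicated drug identifiers are a hard error.
#' @export
readDrugTable <- function(path) {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
    need <- c("drug_id", "name", "targets", "atc_codes")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("drug table misses column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$drug_id))
        stop("duplicate drug_id: ",
             paste(unique(df$drug_id[duplicated(df$drug_id)]),
                   collapse = ", "))
    atc <- .splitMulti(df$atc_codes)
    for (i in seq_along(atc)) {
        bad <- atc[[i]][!grepl(.ATC_REGEX, atc[[i]])]
        if (length(bad)) {
            warning(sprintf("row %d (%s): dropping malformed ATC code(s) %s",
                            i, df$drug_id[i], paste(bad, collapse = ", ")))
            atc[[i]] <- setdiff(atc[[i]], bad)
        }
    }
    o <- order(df$drug_id)
    DrugSet(df$drug_id[o], df$name[o],
            targets = .splitMulti(df$targets)[o], atcCodes = atc[o])
}

#' Write a drug table
#'
#' Inverse of \code{\link{readDrugTable}}; multi-value cells are
#' semicolon-joined with no quoting so round trips are bit-exact.
#'
#' @param drugs a \code{DrugSet}.
#' @param path output TSV path.
#' @export
writeDrugTable <- function(drugs, path) {
    df <- data.frame(
        drug_id = drugIds(drugs),
        name = unname(drugNames(drugs)),
        targets = .joinMulti(as.list(targets(drugs))),
        atc_codes = .joinMulti(as.list(atcCodes(drugs))),
        check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' MSigDB dialect: each tab-separated line is set name, description, then
#' one or more genes. Duplicate genes within a line are de-duplicated; the
#' universe is the union over all sets. Sets are returned sorted by name.
#'
#' @param path path to the GMT file.
#' @return a \code{GeneSetCollection}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("GMT file is empty: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("GMT line(s) with fewer than 3 fields: line ",
             paste(which(nf < 3L), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(sets) <- vapply(fields, `[[`, character(1L), 1L)
    if (anyDuplicated(names(sets)))
        stop("duplicate gene set name(s): ",
             paste(unique(names(sets)[duplicated(names(sets))]),
                   collapse = ", "))
    GeneSetCollection(sets[order(names(sets))])
}

#' Write a GMT gene-set file
#'
#' @param collection a \code{GeneSetCollection}.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @export
writeGmt <- function(collection, path, descriptions = names(collection)) {
    sets <- as.list(geneSets(collection))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1L))
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene-effect matrix with its lineage map
#'
#' The CSV uses screen orientation: first column is the cell-line
#' identifier, remaining columns are gene symbols, cells are real numbers
#' or empty (missing). Missing entries stay \code{NA} and are excluded from
#' all threshold comparisons downstream. Rows and gene columns are sorted
#' by identifier so the reader is order-independent.
#'
#' @param path path to the CSV matrix.
#' @param lineagePath path to a TSV with columns \code{cell_line},
#'   \code{cancer_label}; alternatively pass a named character vector via
#'   \code{lineage}.
#' @param lineage named character vector (cell line -> cancer label), used
#'   when \code{lineagePath} is NULL.
#' @return a \code{GeneEffectMatrix}.
#' @export
readGeneEffects <- function(path, lineagePath = NULL, lineage = NULL) {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE)
    if (ncol(df) < 2L) stop("gene-effect CSV needs at least one gene column")
    genes <- colnames(df)[-1L]
    if (anyDuplicated(genes))
        stop("repeated gene column(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    lines <- df[[1L]]
    if (anyDuplicated(lines))
        stop("repeated cell line(s): ",
             paste(unique(lines[duplicated(lines)]), collapse = ", "))
    raw <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    bad <- which(is.na(num) & nzchar(raw), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric cell at row %d (%s), column '%s'",
                     bad[1L, 1L], lines[bad[1L, 1L]], genes[bad[1L, 2L]]))
    dimnames(num) <- list(lines, genes)
    num <- num[order(lines), order(genes), drop = FALSE]
    if (is.null(lineage)) {
        if (is.null(lineagePath))
            stop("either lineagePath or lineage must be supplied")
        lineage <- readLineage(lineagePath)
    }
    GeneEffectMatrix(num, lineage)
}

#' Write a gene-effect matrix (and optionally its lineage map)
#'
#' Numbers are serialised with \code{\%.17g} so doubles round-trip exactly;
#' missing entries become empty cells.
#'
#' @param gem a \code{GeneEffectMatrix}.
#' @param path output CSV path.
#' @param lineagePath optional TSV path for the lineage map.
#' @export
writeGeneEffects <- function(gem, path, lineagePath = NULL) {
    m <- t(effectScores(gem))  # back to screen orientation
    chr <- array("", dim = dim(m), dimnames = dimnames(m))
    ok <- !is.na(m)
    chr[ok] <- sprintf("%.17g", m[ok])
    df <- data.frame(cell_line = rownames(m), chr,
                     check.names = FALSE, row.names = NULL)
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(lineagePath)) writeLineage(lineage(gem), lineagePath)
    invisible(path)
}

#' Read a lineage map
#' @param path TSV with columns \code{cell_line}, \code{cancer_label}.
#' @return named character vector (cell line -> cancer label).
#' @export
readLineage <- function(path) {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
    need <- c("cell_line", "cancer_label")
    if (!all(need %in% colnames(df)))
        stop("lineage map needs columns: ", paste(need, collapse = ", "))
    stats::setNames(df$cancer_label, df$cell_line)
}

#' Write a lineage map
#' @param lineage named character vector (cell line -> cancer label).
#' @param path output TSV path.
#' @export
writeLineage <- function(lineage, path) {
    utils::write.table(
        data.frame(cell_line = names(lineage),
                   cancer_label = unname(lineage)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a seed list
#'
#' Plain text, one drug identifier per line.
#'
#' @param path input path.
#' @param cancer cancer label for the resulting \code{SeedSet}.
#' @param drugSet optional \code{DrugSet} for member resolution.
#' @return a \code{SeedSet}.
#' @export
readSeedList <- function(path, cancer, drugSet = NULL) {
    ids <- readLines(path)
    ids <- ids[nzchar(trimws(ids))]
    SeedSet(cancer, trimws(ids), drugSet = drugSet)
}

#' Write a seed list
#' @param seeds a \code{SeedSet}.
#' @param path output path.
#' @export
writeSeedList <- function(seeds, path) {
    writeLines(drugIds(seeds), path)
    invisible(path)
}
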