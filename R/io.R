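#' Write / read genotype tables
#'
#' The genotype TSV dialect has one row per marker: \code{marker_id},
#' \code{group_truth} (true or assigned linkage group, NA when unknown), then
#' one genotype column per individual with entries aa/ab/bb/NA.  Individual
#' columns are named \code{<family>_<role-or-offspring-id>}; roles are
#' recovered from the \code{_mother}/\code{_father} suffix and the family
#' from the prefix before the first underscore-delimited role token.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file.
#' @return \code{writeGenotypes}: the path, invisibly; \code{readGenotypes}:
#'   a [GenotypeMatrix-class].
#' @export
writeGenotypes <- function(x, path) {
  mk <- markerInfo(x)
  grp <- if ("true_group" %in% names(mk)) mk$true_group else NA_character_
  df <- data.frame(marker_id = mk$marker_id, group_truth = grp,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(genotypes(x), stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeGenotypes
#' @param individuals optional data.frame (id, family, role) overriding the
#'   column-name convention.
#' @export
readGenotypes <- function(path, individuals = NULL) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      na.strings = "NA", check.names = FALSE),
    error = function(e) stop("malformed genotype file '", path, "': ",
                             conditionMessage(e)))
  need <- c("marker_id", "group_truth")
  if (!all(need %in% names(df)))
    stop("genotype file must start with columns marker_id, group_truth (line 1)")
  ids <- setdiff(names(df), need)
  g <- as.matrix(df[, ids, drop = FALSE])
  bad <- !is.na(g) & !(tolower(g) %in% c(GT_LEVELS, "ba"))
  if (any(bad)) {
    row <- which(apply(bad, 1L, any))[1L]
    stop(sprintf("invalid genotype symbol in '%s' at data line %d", path, row))
  }
  if (is.null(individuals)) {
    role <- ifelse(grepl("_mother$", ids), "mother",
                   ifelse(grepl("_father$", ids), "father", "offspring"))
    fam <- sub("_(mother|father|off.*)$", "", ids)
    individuals <- data.frame(id = ids, family = fam, role = role,
                              stringsAsFactors = FALSE)
  }
  markers <- data.frame(marker_id = df$marker_id,
                        true_group = as.character(df$group_truth),
                        stringsAsFactors = FALSE)
  rownames(g) <- df$marker_id
  genotypeMatrix(g, individuals, markers)
}

#' Minimal VCF genotype ingestion
#'
#' Reads the GT field of a VCF via the vcfR package and maps 0/0, 0/1 (or
#' 1/0), 1/1 and missing calls to aa, ab, bb and NA.  Multi-allelic records
#' are dropped.
#'
#' @param path VCF file.
#' @param individuals data.frame (id, family, role) describing the sample
#'   columns; defaults to the column-name convention of [readGenotypes()].
#' @return a [GenotypeMatrix-class].
#' @export
readVcfGenotypes <- function(path, individuals = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v))
  gt <- vcfR::extract.gt(v)[biallelic, , drop = FALSE]
  map <- c("0/0" = "aa", "0|0" = "aa", "0/1" = "ab", "1/0" = "ab",
           "0|1" = "ab", "1|0" = "ab", "1/1" = "bb", "1|1" = "bb")
  g <- matrix(unname(map[gt]), nrow = nrow(gt), dimnames = dimnames(gt))
  genotypeMatrix(g, individuals)
}

#' Write a filter ledger as TSV and JSON
#'
#' @param ledger a [FilterLedger-class].
#' @param path output path; \code{.tsv} and \code{.json} siblings are
#'   written when \code{path} has no extension, otherwise the named format.
#' @return invisible character vector of files written.
#' @export
writeLedger <- function(ledger, path) {
  files <- character()
  base <- sub("\\.(tsv|json)$", "", path)
  st <- ledgerSteps(ledger)
  if (!grepl("\\.json$", path)) {
    utils::write.table(st, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, paste0(base, ".tsv"))
  }
  if (!grepl("\\.tsv$", path)) {
    jsonlite::write_json(list(initial_snps = ledger@initialSnps,
                              initial_individuals = ledger@initialIndividuals,
                              steps = st),
                         paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, paste0(base, ".json"))
  }
  invisible(files)
}

#' Read / write anchor tables
#' @param anchors data.frame marker_id, linkage_group.
#' @param path TSV path.
#' @export
writeAnchors <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnchors
#' @export
readAnchors <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Write parental maps as a tidy TSV
#'
#' One row per ordered marker: parent, sex, group, rank, marker_id,
#' position_cM (2 decimals), ambiguous.
#'
#' @param maps list of [ParentalMap-class] objects.
#' @param path TSV path.
#' @export
writeMaps <- function(maps, path) {
  df <- do.call(rbind, lapply(maps, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMaps
#' @export
readMaps <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(group = "character"))
}

#' MapChart-compatible text rendering of maps
#'
#' Emits one block per map: a \code{group <id>} header line followed by
#' \code{<marker> <position>} lines with positions to one decimal, the layout
#' consumed by linkage-map drawing tools.
#'
#' @param maps list of [ParentalMap-class] objects.
#' @param path output text file.
#' @export
writeMapChart <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in maps) {
    writeLines(sprintf("group %s_%s", m@parent, m@group), con)
    writeLines(sprintf("%s %.1f", m@markers, m@positions), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write BLAST-tabular hit tables
#'
#' Six-column BLAST-style TSV: query, target, identity, length, evalue,
#' bitscore (header row mandatory in this dialect).
#'
#' @param hits hit data.frame.
#' @param path TSV path.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("query", "target", "identity", "length", "evalue", "bitscore")
  if (!all(need %in% names(df)))
    stop("hit table must have columns ", paste(need, collapse = ", "))
  df
}

#' Write interval profiles as a tidy TSV
#' @param profiles list of [IntervalProfile-class] objects.
#' @param path TSV path.
#' @export
writeProfiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(parent = p@parent, sex = p@sex, group = p@group,
               interval = seq_along(p@percent),
               percent = round(p@percent, 3), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
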