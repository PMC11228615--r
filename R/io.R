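# Dataset input/output and curation filters.

.KR_TAXA <- c("actinobacteria", "myxobacteria", "cyanobacteria", "other")
.KR_LABELS <- c("A0","A1","A2","B0","B1","B2","C0","C1","C2",
                "EDH","ZDH","ER_product","unknown")

#' Construct / validate a KR dataset
#'
#' A KR dataset is a data frame with one row per KR record: \code{id}
#' (unique), \code{sequence} (amino acids, X allowed), \code{taxon_group},
#' \code{module_domains} (comma-separated N-to-C codes),
#' \code{dh_active} (\code{active}/\code{inactive}/\code{absent}),
#' \code{product_label}, \code{bgc_product}, \code{strain},
#' \code{alpha_substituted} and the curation flags
#' \code{relative_config_only}, \code{stereochem_uninferable},
#' \code{loading_module}.  Missing columns are filled with defaults;
#' invariants are enforced: \code{dh_active} is \code{absent} exactly when
#' the module has no DH domain, and double-bond/alkane product labels
#' (EDH/ZDH/ER_product) require a DH or ER domain.
#'
#' @param df A data frame with at least \code{id} and \code{sequence}.
#' @return The validated data frame with class \code{kr_dataset}.
#' @export
kr_dataset <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "sequence") %in% names(df)))
  if (anyDuplicated(df$id))
    stop("duplicate record ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ","),
         call. = FALSE)
  for (i in seq_len(nrow(df))) .check_aa(df$sequence[i], df$id[i])

  defaults <- list(taxon_group = "other", module_domains = "KS,AT,KR,ACP",
                   dh_active = NA_character_, product_label = "unknown",
                   bgc_product = NA_character_, strain = NA_character_,
                   alpha_substituted = NA,
                   relative_config_only = FALSE,
                   stereochem_uninferable = FALSE,
                   loading_module = FALSE)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))

  df$taxon_group[!df$taxon_group %in% .KR_TAXA] <- "other"
  bad_lab <- !df$product_label %in% .KR_LABELS
  if (any(bad_lab)) {
    warning("unknown product labels set to 'unknown': ",
            paste(unique(df$product_label[bad_lab]), collapse = ","),
            call. = FALSE)
    df$product_label[bad_lab] <- "unknown"
  }

  has_dh <- vapply(strsplit(df$module_domains, ","),
                   function(d) "DH" %in% trimws(toupper(d)), logical(1))
  has_er <- vapply(strsplit(df$module_domains, ","),
                   function(d) "ER" %in% trimws(toupper(d)), logical(1))
  df$dh_active[!has_dh] <- "absent"
  df$dh_active[has_dh & (is.na(df$dh_active) | df$dh_active == "absent")] <-
    "active"

  dh_labels <- df$product_label %in% c("EDH", "ZDH", "ER_product")
  viol <- dh_labels & !(has_dh | has_er)
  if (any(viol)) {
    warning("EDH/ZDH/ER_product labels require a DH or ER domain; ",
            "set to 'unknown' for: ", paste(df$id[viol], collapse = ","),
            call. = FALSE)
    df$product_label[viol] <- "unknown"
  }
  structure(df, class = c("kr_dataset", "data.frame"))
}

#' Read a KR dataset from FASTA + annotation TSV
#'
#' Sequences come from the FASTA (record id = first word of each header);
#' per-record annotations come from a tab-separated table with a header
#' row, UTF-8, \code{#} comment lines allowed, keyed by an \code{id}
#' column.  FASTA entries with no annotation row get defaults (with a
#' warning); annotation rows with no FASTA entry are reported as a
#' warning.  Duplicate ids are an error.
#'
#' @param fasta_path Path to an amino-acid FASTA file.
#' @param annotations_path Path to the annotation TSV (optional: omit for
#'   all-defaults records).
#' @return A \code{\link{kr_dataset}}.
#' @export
read_kr_dataset <- function(fasta_path, annotations_path = NULL) {
  aa <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                 error = function(e)
                   stop("malformed FASTA '", fasta_path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(aa) == 0L) stop("FASTA contains no records", call. = FALSE)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","), call. = FALSE)
  df <- data.frame(id = ids, sequence = as.character(aa),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL

  if (!is.null(annotations_path)) {
    ann <- utils::read.delim(annotations_path, comment.char = "#",
                             stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
    if (!"id" %in% names(ann))
      stop("annotation table lacks an 'id' column", call. = FALSE)
    orphans <- setdiff(ann$id, df$id)
    if (length(orphans) > 0L)
      warning("annotation rows with no FASTA entry: ",
              paste(orphans, collapse = ","), call. = FALSE)
    missing <- setdiff(df$id, ann$id)
    if (length(missing) > 0L)
      warning("FASTA entries with no annotation row (defaults used): ",
              paste(missing, collapse = ","), call. = FALSE)
    keep <- setdiff(names(ann), c("id", "sequence"))
    df <- merge(df, ann[, c("id", keep), drop = FALSE], by = "id",
                all.x = TRUE, sort = FALSE)
    df <- df[match(ids, df$id), , drop = FALSE]
    rownames(df) <- NULL
    for (flag in c("relative_config_only", "stereochem_uninferable",
                   "loading_module"))
      if (flag %in% names(df)) df[[flag]] <- isTRUE_vec(df[[flag]])
    if ("alpha_substituted" %in% names(df))
      df$alpha_substituted <- as.logical(df$alpha_substituted)
    if ("module_domains" %in% names(df))
      df$module_domains[is.na(df$module_domains)] <- "KS,AT,KR,ACP"
    if ("product_label" %in% names(df))
      df$product_label[is.na(df$product_label)] <- "unknown"
    if ("taxon_group" %in% names(df))
      df$taxon_group[is.na(df$taxon_group)] <- "other"
  }
  kr_dataset(df)
}

isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' Write a KR dataset to FASTA + annotation TSV
#'
#' @param records A \code{\link{kr_dataset}}.
#' @param fasta_path,annotations_path Output paths.
#' @export
write_kr_dataset <- function(records, fasta_path, annotations_path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, fasta_path)
  ann <- as.data.frame(records)[, setdiff(names(records), "sequence"),
                                drop = FALSE]
  utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, annotations_path))
}

#' Curate a KR dataset
#'
#' Applies the dataset screening rules used to assemble a
#' sequence-stereochemistry training set: records whose module lacks a KR
#' are dropped (\code{no_KR}); modules with duplicated KRs or otherwise
#' non-canonical architectures are dropped (\code{unconventional_module});
#' loading modules are dropped (\code{loading_module}); records flagged as
#' having only relative configurations, or stereochemistry that cannot be
#' inferred from the product (e.g. later aromatization), are dropped
#' (\code{relative_config_only}, \code{stereochem_uninferable}); finally,
#' among the survivors, later records sharing the same \code{dedupe_key}
#' (same final product from different producer strains) are dropped,
#' keeping the first in input order (\code{duplicate_product_source}).
#'
#' @param records A \code{\link{kr_dataset}}.
#' @param dedupe_key Field used for duplicate-product removal
#'   (default \code{"bgc_product"}; \code{NA} keys are never deduplicated).
#' @return A \code{kr_curation} list: \code{kept} (ids), \code{dropped}
#'   (data frame of id, reason) and \code{records} (the kept subset).
#' @export
curate_kr <- function(records, dedupe_key = "bgc_product") {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n > 0L) {
    doms <- strsplit(records$module_domains, ",")
    doms <- lapply(doms, function(d) trimws(toupper(d)))
    n_kr <- vapply(doms, function(d) sum(d == "KR"), integer(1))
    mtyp <- .classify_modules(records$module_domains)

    reason[records$loading_module] <- "loading_module"
    reason[is.na(reason) & n_kr == 0L] <- "no_KR"
    reason[is.na(reason) & (n_kr >= 2L | mtyp == "unconventional")] <-
      "unconventional_module"
    reason[is.na(reason) & records$relative_config_only] <-
      "relative_config_only"
    reason[is.na(reason) & records$stereochem_uninferable] <-
      "stereochem_uninferable"

    key <- records[[dedupe_key]]
    surv <- which(is.na(reason))
    dup <- surv[duplicated(key[surv], incomparables = NA)]
    reason[dup] <- "duplicate_product_source"
  }
  kept <- records$id[is.na(reason)]
  dropped <- data.frame(id = records$id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  structure(list(kept = kept, dropped = dropped,
                 records = structure(records[is.na(reason), , drop = FALSE],
                                     class = class(records))),
            class = "kr_curation")
}

#' @export
print.kr_curation <- function(x, ...) {
  cat(sprintf("KR curation: %d kept, %d dropped\n", length(x$kept),
              nrow(x$dropped)))
  if (nrow(x$dropped))
    print(table(x$dropped$reason))
  invisible(x)
}

#' Dataset composition statistics
#'
#' Counts and within-stratum percentages of product labels, stratified by
#' taxon group and module type (the module type is derived from each
#' record's domain string).
#'
#' @param records A \code{\link{kr_dataset}}.
#' @return A \code{kr_stats} data frame: \code{taxon_group},
#'   \code{module_type}, \code{product_label}, \code{n}, \code{percent}
#'   (percentages sum to 100 within each taxon-by-module stratum).
#' @export
kr_dataset_stats <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  mtype <- .classify_modules(records$module_domains)
  tab <- as.data.frame(table(taxon_group = records$taxon_group,
                             module_type = mtype,
                             product_label = records$product_label),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  stratum <- paste(tab$taxon_group, tab$module_type)
  tot <- tapply(tab$n, stratum, sum)
  tab$percent <- 100 * tab$n / as.numeric(tot[stratum])
  tab <- tab[order(tab$taxon_group, tab$module_type, tab$product_label), ]
  rownames(tab) <- NULL
  structure(tab, class = c("kr_stats", "data.frame"))
}

#' Write a stats/prediction table as TSV or JSON
#'
#' @param x A data frame (e.g. from \code{\link{kr_dataset_stats}}).
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_kr_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(x), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
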