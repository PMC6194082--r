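# Plain-text file formats: fraction CSV and OTU TSV.
# All files are UTF-8 with "." decimal; densities carry >= 4 decimals so a
# 12-fraction gradient over 1.687-1.770 g/mL stays resolvable.

#' Read a gradient fraction table
#'
#' CSV with header `tube_id,treatment,timepoint_days,fraction,density_g_ml,
#' dna_conc,failed`; rows are grouped by `tube_id` into one
#' [fraction_set()] per tube. Densities not ordered heavy-first are
#' re-sorted with a warning. `failed` accepts TRUE/FALSE, 0/1, yes/no.
#'
#' @param path path to the CSV file.
#' @return named list of [fraction_set()] objects, one per tube.
#' @export
read_fraction_table <- function(path) {
  if (!file.exists(path)) stop_domain("fraction table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("tube_id", "treatment", "timepoint_days", "fraction",
            "density_g_ml", "dna_conc", "failed")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_domain("fraction table missing column(s): ",
                paste(miss, collapse = ", "))
  }
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop_domain("non-numeric ", col, " at line ", line[bad[1]],
                  ": '", df[[col]][bad[1]], "'")
    }
    v
  }
  density <- num("density_g_ml")
  conc <- num("dna_conc")
  tp <- num("timepoint_days")
  frac <- num("fraction")
  if (any(!is_wholenumber(frac))) {
    bad <- which(!is_wholenumber(frac))[1]
    stop_domain("fraction id must be an integer at line ", line[bad])
  }
  failed_map <- c("true" = TRUE, "false" = FALSE, "1" = TRUE, "0" = FALSE,
                  "yes" = TRUE, "no" = FALSE, "t" = TRUE, "f" = FALSE)
  failed <- failed_map[tolower(trimws(df$failed))]
  if (any(is.na(failed))) {
    bad <- which(is.na(failed))[1]
    stop_domain("unparseable 'failed' value at line ", line[bad],
                ": '", df$failed[bad], "'")
  }
  dup <- duplicated(df[c("tube_id", "fraction")])
  if (any(dup)) {
    stop_domain("duplicate (tube_id, fraction) at line ", line[which(dup)[1]])
  }
  tubes <- split(seq_len(nrow(df)), df$tube_id)
  out <- lapply(tubes, function(ix) {
    trt <- unique(df$treatment[ix])
    if (length(trt) != 1L) {
      stop_domain("tube ", df$tube_id[ix[1]], " mixes treatments")
    }
    fraction_set(fraction = as.integer(frac[ix]), density = density[ix],
                 dna_conc = conc[ix], failed = unname(failed[ix]),
                 treatment = trt, timepoint = tp[ix][1],
                 tube_id = df$tube_id[ix[1]])
  })
  out
}

#' Write gradient fraction sets as CSV
#'
#' Inverse of [read_fraction_table()].
#'
#' @param fs a [fraction_set()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(fs, path) {
  if (inherits(fs, "fraction_set")) fs <- list(fs)
  rows <- do.call(rbind, lapply(fs, function(f) {
    data.frame(tube_id = f$tube_id, treatment = f$treatment,
               timepoint_days = f$timepoint,
               fraction = f$fractions$fraction,
               density_g_ml = sprintf("%.5f", f$fractions$density),
               dna_conc = f$fractions$dna_conc,
               failed = f$fractions$failed, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OTU count table with sample metadata
#'
#' TSV whose first columns are `sample`, `role`, `treatment`,
#' `timepoint_days` (plus an optional `fraction`), followed by one integer
#' count column per OTU.
#'
#' @param path path to the TSV file.
#' @return a [otu_table()].
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop_domain("OTU table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta_cols <- intersect(c("sample", "role", "treatment", "timepoint_days",
                           "fraction"), names(df))
  if (!all(c("sample", "role") %in% meta_cols)) {
    stop_domain("OTU table must start with 'sample' and 'role' columns")
  }
  count_cols <- setdiff(names(df), meta_cols)
  if (!length(count_cols)) stop_domain("no OTU count columns found")
  counts <- as.matrix(df[count_cols])
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(!is_wholenumber(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 |
                   !is_wholenumber(counts), arr.ind = TRUE)[1, ]
    stop_domain("invalid count '", df[[count_cols[bad[2]]]][bad[1]],
                "' for sample '", df$sample[bad[1]], "', OTU '",
                count_cols[bad[2]], "' (counts must be non-negative integers)")
  }
  rownames(counts) <- df$sample
  otu_table(counts, df[meta_cols])
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()].
#'
#' @param table a [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "sip_otu"))
  out <- cbind(table$meta, as.data.frame(table$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
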