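#' Validate embryo records
#'
#' Enforces the structural invariants of an embryo-record table: required
#' columns present; trait fields missing whenever the embryo died;
#' observed hatching times beyond the 240.5 degree-day treatment start;
#' positive yolk volumes consistent with the measured dimensions under the
#' declared volume formula.
#'
#' @param records Embryo-record data frame.
#' @param yolk_coef Volume coefficient used for the consistency check.
#' @return `records`, invisibly. Errors name the offending rows.
#' @export
validate_records <- function(records, yolk_coef = pi / 6) {
  need <- c("sire_id", "dam_id", "raw_group", "analysis_group",
            "replicate_index", "survived", "hatch_dd", "length_mm",
            "yolk_len_mm", "yolk_width_mm", "yolk_vol_mm3")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("records table is empty", call. = FALSE)
  if (any(is.na(records$survived))) {
    stop("survived must be TRUE/FALSE for every row", call. = FALSE)
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("invalid records (%s) at row(s): %s", what,
                   paste(utils::head(idx, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  dead <- !records$survived
  traits <- c("hatch_dd", "length_mm", "yolk_len_mm", "yolk_width_mm",
              "yolk_vol_mm3")
  has_trait <- Reduce(`|`, lapply(records[traits], function(x) !is.na(x)))
  bad_row(dead & has_trait, "trait values on dead embryos")
  bad_row(!is.na(records$hatch_dd) & records$hatch_dd <= 240.5,
          "hatch_dd at or before the 240.5 DD treatment start")
  bad_row(!is.na(records$yolk_vol_mm3) & records$yolk_vol_mm3 <= 0,
          "non-positive yolk volume")
  ok <- !is.na(records$yolk_vol_mm3) & !is.na(records$yolk_len_mm) &
    !is.na(records$yolk_width_mm)
  if (any(ok)) {
    expect <- yolk_coef * records$yolk_len_mm[ok] *
      records$yolk_width_mm[ok]^2
    rel <- abs(records$yolk_vol_mm3[ok] - expect) / pmax(expect, 1e-12)
    bad_row(seq_len(nrow(records)) %in% which(ok)[rel > 1e-4],
            "yolk volume inconsistent with dimensions")
  }
  invisible(records)
}

#' Write embryo records to CSV
#'
#' UTF-8 comma-separated text with a header row; missing values are empty
#' cells. The round trip through [read_records()] is lossless.
#'
#' @param records Embryo-record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read embryo records from CSV
#'
#' Parses a phenotype table written by [write_records()] (or assembled by
#' hand in the same layout). Empty cells become missing values; cells that
#' fail numeric parsing raise an error naming the row; the structural
#' invariants are enforced unless `validate = FALSE`.
#'
#' @param path CSV file path.
#' @param validate Run [validate_records()] on the result?
#' @return Embryo-record data frame.
#' @export
read_records <- function(path, validate = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = TRUE)
  num_cols <- c("replicate_index", "hatch_dd", "length_mm", "yolk_len_mm",
                "yolk_width_mm", "yolk_vol_mm3")
  for (cn in intersect(num_cols, names(raw))) {
    x <- raw[[cn]]
    x[x == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("cannot parse column '%s' at row(s): %s", cn,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    raw[[cn]] <- parsed
  }
  if ("survived" %in% names(raw)) {
    sv <- toupper(trimws(raw$survived))
    parsed <- ifelse(sv %in% c("TRUE", "T", "1"), TRUE,
                     ifelse(sv %in% c("FALSE", "F", "0"), FALSE, NA))
    bad <- which(!is.na(sv) & sv != "" & is.na(parsed))
    if (length(bad)) {
      stop("cannot parse column 'survived' at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    raw$survived <- parsed
  }
  if (validate) validate_records(raw)
  raw
}
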