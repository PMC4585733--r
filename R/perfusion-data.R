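#' @importFrom stats median coef cov lm predict rnorm runif sd setNames var vcov
#' @importFrom utils read.table write.table
NULL

TISSUE_LEVELS <- c("PT", "SE", "TM")
BLOOD_LEVELS <- c("native", "heparinized")

# Canonical on-disk column names, in order, mapped to internal names.
PERFUSION_COLUMNS <- c(
  subject_id = "subject_id",
  shear_rate = "shear_rate_s1",
  time_min = "time_min",
  hematocrit = "hematocrit_pct",
  platelet_conc = "platelets_e3_per_ul",
  blood = "blood",
  tissue = "tissue",
  stenosis = "stenosis",
  deposition = "deposition_e6_per_cm2"
)

#' Construct a validated perfusion-experiment table
#'
#' The central data container: one row per perfusion experiment in a
#' Badimon-type chamber. Internally hematocrit is stored as a volume fraction
#' in (0, 1); platelet concentration in 10^3 platelets/ul; perfusion time in
#' minutes; wall shear rate in 1/s; platelet deposition in 10^6 platelets/cm^2
#' (`NA` for records awaiting prediction).
#'
#' @param subject_id character labels identifying the blood donor (animal);
#'   these define the grouping used by leave-one-subject-out cross-validation.
#' @param shear_rate wall shear rate in 1/s, strictly positive.
#' @param time_min perfusion time in minutes, strictly positive.
#' @param hematocrit red-cell volume fraction, strictly inside (0, 1).
#' @param platelet_conc platelet concentration in 10^3 platelets/ul, positive.
#' @param blood `"native"` or `"heparinized"`.
#' @param tissue thrombogenic substrate: `"PT"` (pig tendon), `"SE"`
#'   (subendothelium) or `"TM"` (tunica media).
#' @param stenosis logical; `TRUE` marks the 80 percent stenosis condition,
#'   whose effective wall shear rate is supplied through `shear_rate`.
#' @param deposition measured platelet deposition in 10^6 platelets/cm^2,
#'   strictly positive when present (all models work on log10 deposition),
#'   `NA` when unknown.
#' @param provenance free-text description of where the records came from.
#'
#' @return A data.frame of class `perfusion_table`.
#' @export
perfusion_table <- function(subject_id, shear_rate, time_min, hematocrit,
                            platelet_conc, blood, tissue, stenosis,
                            deposition = NA_real_, provenance = "constructed") {
  x <- data.frame(
    subject_id = as.character(subject_id),
    shear_rate = as.numeric(shear_rate),
    time_min = as.numeric(time_min),
    hematocrit = as.numeric(hematocrit),
    platelet_conc = as.numeric(platelet_conc),
    blood = as.character(blood),
    tissue = as.character(tissue),
    stenosis = as.logical(stenosis),
    deposition = as.numeric(deposition),
    stringsAsFactors = FALSE
  )
  attr(x, "provenance") <- provenance
  class(x) <- c("perfusion_table", "data.frame")
  validate_perfusion_table(x)
  x
}

#' Validate a perfusion table
#'
#' Checks every record against the domain invariants (positive shear rate,
#' time and platelet concentration; hematocrit a fraction in (0, 1); known
#' tissue and blood levels; strictly positive deposition where present).
#'
#' @param x a `perfusion_table` (or a data.frame with its columns).
#' @return `x`, invisibly, if valid; otherwise an error naming the violation.
#' @export
validate_perfusion_table <- function(x) {
  needed <- names(PERFUSION_COLUMNS)
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    stop_domain("perfusion table is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  if (nrow(x) == 0L) stop_domain("perfusion table has no records")
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      stop_domain(msg, " (row ", which(cond)[1L], ")")
    }
  }
  bad(is.na(x$subject_id) | x$subject_id == "", "empty subject_id")
  bad(!is.finite(x$shear_rate) | x$shear_rate <= 0, "shear_rate must be > 0")
  bad(!is.finite(x$time_min) | x$time_min <= 0, "time_min must be > 0")
  bad(!is.finite(x$hematocrit) | x$hematocrit <= 0 | x$hematocrit >= 1,
      "hematocrit must be a fraction strictly inside (0, 1)")
  bad(!is.finite(x$platelet_conc) | x$platelet_conc <= 0,
      "platelet_conc must be > 0")
  bad(!x$tissue %in% TISSUE_LEVELS,
      paste0("tissue must be one of ", paste(TISSUE_LEVELS, collapse = ", ")))
  bad(!x$blood %in% BLOOD_LEVELS,
      paste0("blood must be one of ", paste(BLOOD_LEVELS, collapse = ", ")))
  bad(is.na(x$stenosis), "stenosis flag must be TRUE or FALSE")
  bad(!is.na(x$deposition) & (x$deposition <= 0 | !is.finite(x$deposition)),
      "deposition must be strictly positive when present")
  invisible(x)
}

#' @export
print.perfusion_table <- function(x, ...) {
  cat(sprintf("Perfusion table: %d records, %d subject(s) [%s]\n",
              nrow(x), length(unique(x$subject_id)),
              paste(sort(unique(x$subject_id)), collapse = ", ")))
  cat(sprintf("  tissues: %s; stenosed records: %d; with deposition: %d\n",
              paste(sort(unique(x$tissue)), collapse = "/"),
              sum(x$stenosis), sum(!is.na(x$deposition))))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  provenance:", prov, "\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a perfusion table from delimited text
#'
#' Expects the canonical header `subject_id, shear_rate_s1, time_min,
#' hematocrit_pct, platelets_e3_per_ul, blood, tissue, stenosis,
#' deposition_e6_per_cm2`. Hematocrit is given in percent on disk and divided
#' by 100 on read. The deposition column may contain `NA` for
#' prediction-only rows.
#'
#' @param path file to read.
#' @param delim field delimiter; `","` (default) or `"\t"`.
#' @return a validated [perfusion_table] preserving row order.
#' @export
read_perfusion_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(unname(PERFUSION_COLUMNS), names(raw))
  if (length(missing) > 0L) {
    stop_domain("missing column(s) in ", path, ": ",
                paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop_domain("no data rows in ", path)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "NA" & is.na(v))
    if (length(bad) > 0L) {
      stop_domain("unparseable numeric value in column ", col,
                  ", data row ", bad[1L])
    }
    v
  }
  perfusion_table(
    subject_id = raw$subject_id,
    shear_rate = num("shear_rate_s1"),
    time_min = num("time_min"),
    hematocrit = num("hematocrit_pct") / 100,
    platelet_conc = num("platelets_e3_per_ul"),
    blood = raw$blood,
    tissue = raw$tissue,
    stenosis = as.logical(raw$stenosis),
    deposition = num("deposition_e6_per_cm2"),
    provenance = path
  )
}

#' Write a perfusion table as delimited text
#'
#' Serializes with the canonical header (hematocrit written in percent) at
#' full precision, so `read_perfusion_table(write_perfusion_table(x))` is the
#' identity.
#'
#' @param x a validated [perfusion_table].
#' @param path output file.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_perfusion_table <- function(x, path, delim = ",") {
  validate_perfusion_table(x)
  out <- data.frame(
    subject_id = x$subject_id,
    shear_rate_s1 = format(x$shear_rate, digits = 17, trim = TRUE),
    time_min = format(x$time_min, digits = 17, trim = TRUE),
    hematocrit_pct = format(x$hematocrit * 100, digits = 17, trim = TRUE),
    platelets_e3_per_ul = format(x$platelet_conc, digits = 17, trim = TRUE),
    blood = x$blood,
    tissue = x$tissue,
    stenosis = x$stenosis,
    deposition_e6_per_cm2 = ifelse(is.na(x$deposition), "NA",
                                   format(x$deposition, digits = 17,
                                          trim = TRUE)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert platelet concentration to SI units
#'
#' Converts from the chamber convention of 10^3 platelets/ul to platelets/m^3
#' (1 ul = 1e-9 m^3, so the factor is 1e12).
#'
#' @param c concentration in 10^3 platelets/ul, strictly positive.
#' @return concentration in platelets/m^3.
#' @export
to_si_concentration <- function(c) {
  if (any(!is.finite(c) | c <= 0)) stop_domain("concentration must be > 0")
  c * 1e12
}

#' Convert platelet deposition to SI units
#'
#' Converts from 10^6 platelets/cm^2 to platelets/m^2 (factor 1e10).
#'
#' @param p deposition in 10^6 platelets/cm^2, strictly positive.
#' @return deposition in platelets/m^2.
#' @export
to_si_deposition <- function(p) {
  if (any(!is.finite(p) | p <= 0)) stop_domain("deposition must be > 0")
  p * 1e10
}

#' Chamber substrate geometry
#'
#' The exposed substrate is treated as a flat plate of length `substrate_length`
#' (the streamwise extent, the `L` in the boundary-layer flux law) and width
#' `substrate_width`, with deposition area `A = L * W`. The default unrolls a
#' cylindrical conduit of 1 mm diameter over a 2 cm exposed segment.
#'
#' @param substrate_length streamwise substrate length in metres.
#' @param substrate_width substrate width in metres.
#' @return an object of class `chamber_geometry` with fields
#'   `substrate_length`, `substrate_width`, `area` (m^2).
#' @export
chamber_geometry <- function(substrate_length = 0.02,
                             substrate_width = pi * 1e-3) {
  if (substrate_length <= 0 || substrate_width <= 0) {
    stop_domain("substrate dimensions must be > 0")
  }
  structure(
    list(substrate_length = substrate_length,
         substrate_width = substrate_width,
         area = substrate_length * substrate_width),
    class = "chamber_geometry"
  )
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("Chamber substrate: L = %.4g m, W = %.4g m, A = %.4g m^2\n",
              x$substrate_length, x$substrate_width, x$area))
  invisible(x)
}
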