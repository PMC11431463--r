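#' Construct a single-source STR profile
#'
#' An `str_profile` bundles the called (or raw) peaks of one sample with an
#' optional reference genotype for the known donor. Peaks live in a tibble
#' with one row per peak; artefact peaks (non-donor, non-stutter peaks such
#' as co-amplified qPCR targets appearing in a dye lane) are flagged in the
#' `artefact` column rather than removed, so the quality metric can penalise
#' them while completeness statistics ignore them.
#'
#' @param sample Sample identifier (scalar character).
#' @param peaks Data frame with columns `locus`, `allele`, `size_bp`,
#'   `height_rfu` and optionally `dye` and `artefact`.
#' @param reference Optional [reference_genotype()] for the known donor.
#' @return An object of class `str_profile`: a list with elements `sample`,
#'   `peaks` (tibble) and `reference`.
#' @examples
#' p <- str_profile("s1", tibble::tibble(
#'   locus = c("D3S1358", "vWA"), allele = c("15", "17"),
#'   size_bp = c(120, 170), height_rfu = c(800, 650)
#' ))
#' p
#' @export
str_profile <- function(sample, peaks, reference = NULL) {
  stopifnot(is.character(sample), length(sample) == 1L)
  peaks <- tibble::as_tibble(peaks)
  required <- c("locus", "allele", "size_bp", "height_rfu")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    abort(paste0("peak table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "smartpcr_format_error")
  }
  if (!"dye" %in% names(peaks)) peaks$dye <- NA_character_
  if (!"artefact" %in% names(peaks)) peaks$artefact <- FALSE
  peaks$locus <- as.character(peaks$locus)
  peaks$allele <- as.character(peaks$allele)
  if (any(peaks$height_rfu < 0, na.rm = TRUE)) {
    abort("peak heights must be nonnegative", class = "smartpcr_domain_error")
  }
  if (any(peaks$size_bp <= 0, na.rm = TRUE)) {
    abort("fragment sizes must be positive", class = "smartpcr_domain_error")
  }
  if (!is.null(reference) && !inherits(reference, "reference_genotype")) {
    reference <- reference_genotype(reference)
  }
  structure(
    list(sample = sample,
         peaks = peaks[c("locus", "allele", "size_bp", "height_rfu",
                         "dye", "artefact")],
         reference = reference),
    class = "str_profile"
  )
}

#' @export
print.str_profile <- function(x, ...) {
  cat("<str_profile> sample:", x$sample,
      "|", nrow(x$peaks), "peaks",
      if (!is.null(x$reference))
        paste0("| reference: ", expected_allele_count(x$reference),
               " expected alleles"),
      "\n")
  print(x$peaks, ...)
  invisible(x)
}

#' Reference genotype of the known donor
#'
#' Stores the donor's per-locus allele pairs as a tibble of distinct
#' `(locus, allele)` positions. Homozygous loci contribute a single position,
#' so a full GlobalFiler-style single-source genotype with a few homozygous
#' loci has fewer positions than twice the locus count (e.g. 37 positions for
#' 21 autosomal loci with 5 homozygotes).
#'
#' @param genotype Data frame with columns `locus` and `allele`; an optional
#'   `size_bp` column (used by the simulator) and `dye` column are kept.
#' @return A tibble of class `reference_genotype`, one row per distinct
#'   expected allele position.
#' @seealso [expected_allele_count()], [example_reference_genotype()]
#' @export
reference_genotype <- function(genotype) {
  genotype <- tibble::as_tibble(genotype)
  missing_cols <- setdiff(c("locus", "allele"), names(genotype))
  if (length(missing_cols) > 0) {
    abort(paste0("reference genotype is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "smartpcr_format_error")
  }
  genotype$locus <- as.character(genotype$locus)
  genotype$allele <- as.character(genotype$allele)
  genotype <- dplyr::distinct(genotype, .data$locus, .data$allele,
                              .keep_all = TRUE)
  class(genotype) <- c("reference_genotype", class(genotype))
  genotype
}

#' Number of distinct expected allele positions in a reference genotype
#' @param reference A [reference_genotype()].
#' @return Integer count of distinct `(locus, allele)` positions.
#' @export
expected_allele_count <- function(reference) {
  stopifnot(inherits(reference, "reference_genotype"))
  nrow(reference)
}

#' A synthetic 21-locus donor reference genotype
#'
#' A fixed, package-generated single-source genotype covering 21 autosomal
#' STR loci with 16 heterozygous and 5 homozygous loci, giving 37 distinct
#' expected allele positions. Fragment sizes are plausible for a 6-dye
#' megaplex and are used by the simulator's degradation model. This genotype
#' is synthetic: it does not correspond to any real individual.
#'
#' @return A [reference_genotype()] with 37 rows and columns `locus`,
#'   `allele`, `size_bp`, `dye`.
#' @export
example_reference_genotype <- function() {
  het <- list(
    list("D3S1358", c("15", "17"), c(121, 129), "B"),
    list("vWA",     c("16", "18"), c(170, 178), "B"),
    list("D16S539", c("9", "12"),  c(250, 262), "B"),
    list("CSF1PO",  c("10", "11"), c(300, 304), "B"),
    list("D8S1179", c("12", "14"), c(132, 140), "G"),
    list("D21S11",  c("28", "31"), c(195, 207), "G"),
    list("D18S51",  c("13", "16"), c(275, 287), "G"),
    list("D2S441",  c("11", "14"), c(84, 96),   "Y"),
    list("D19S433", c("13", "14"), c(110, 114), "Y"),
    list("FGA",     c("21", "24"), c(230, 242), "Y"),
    list("D22S1045", c("15", "16"), c(105, 108), "R"),
    list("D5S818",  c("11", "12"), c(150, 154), "R"),
    list("D13S317", c("9", "11"),  c(200, 208), "R"),
    list("D7S820",  c("8", "10"),  c(260, 268), "R"),
    list("D10S1248", c("13", "15"), c(95, 103), "P"),
    list("D1S1656", c("12", "15.3"), c(175, 190), "P")
  )
  hom <- list(
    list("TPOX",    "8",  330, "B"),
    list("TH01",    "9.3", 185, "Y"),
    list("SE33",    "27.2", 340, "R"),
    list("D12S391", "20", 225, "P"),
    list("D2S1338", "19", 310, "P")
  )
  rows_het <- purrr::map(het, function(l) {
    tibble::tibble(locus = l[[1]], allele = l[[2]], size_bp = l[[3]],
                   dye = l[[4]])
  })
  rows_hom <- purrr::map(hom, function(l) {
    tibble::tibble(locus = l[[1]], allele = l[[2]], size_bp = l[[3]],
                   dye = l[[4]])
  })
  reference_genotype(dplyr::bind_rows(rows_het, rows_hom))
}

# canonical name for a GeneMapper-style header: lowercase, alphanumeric only
.canon_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.peak_col_map <- c(
  samplefile = "sample", sample = "sample", samplename = "sample",
  dye = "dye",
  marker = "locus", locus = "locus",
  allele = "allele", allele1 = "allele",
  size = "size_bp", sizebp = "size_bp",
  height = "height_rfu", heightrfu = "height_rfu"
)

#' Read a GeneMapper-style peak table
#'
#' Parses a tab- or comma-delimited peak-height export (columns in the style
#' `Sample File`, `Dye`, `Marker`, `Allele`, `Size`, `Height`; header names
#' are matched case- and punctuation-insensitively) into one [str_profile()]
#' per sample. Rows whose height cannot be parsed as a number are dropped and
#' reported, not silently ignored.
#'
#' @param file Path to the delimited file, or a literal string of its
#'   contents.
#' @param dialect `"auto"` (default; sniffs the header line), `"tab"` or
#'   `"comma"`.
#' @param reference Optional [reference_genotype()] attached to every
#'   profile.
#' @return A named list of [str_profile()] objects, one per sample, with a
#'   `rejected` attribute: a tibble (`row`, `sample`, `reason`) describing
#'   any rows that were dropped. Retrieve it with [rejected_rows()].
#' @export
read_peak_table <- function(file, dialect = c("auto", "tab", "comma"),
                            reference = NULL) {
  dialect <- match.arg(dialect)
  if (length(file) == 1L && !file.exists(file) && grepl("[\t\n,]", file)) {
    file <- I(file)
  }
  if (dialect == "auto") {
    first <- readr::read_lines(file, n_max = 1L)
    dialect <- if (grepl("\t", first)) "tab" else "comma"
  }
  delim <- if (dialect == "tab") "\t" else ","
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  canon <- .canon_name(names(raw))
  mapped <- .peak_col_map[canon]
  keep <- !is.na(mapped)
  raw <- raw[keep]
  names(raw) <- mapped[keep]
  raw <- raw[!duplicated(names(raw))]

  required <- c("sample", "locus", "allele", "size_bp", "height_rfu")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("peak table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "smartpcr_format_error")
  }
  if (!"dye" %in% names(raw)) raw$dye <- NA_character_

  height <- suppressWarnings(as.numeric(raw$height_rfu))
  size <- suppressWarnings(as.numeric(raw$size_bp))
  bad <- is.na(height) | is.na(size)
  rejected <- tibble::tibble(
    row = which(bad),
    sample = raw$sample[bad],
    reason = dplyr::if_else(is.na(height[bad]),
                            "unparseable height", "unparseable size")
  )
  ok <- raw[!bad, ]
  ok$height_rfu <- height[!bad]
  ok$size_bp <- size[!bad]

  profiles <- ok |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      str_profile(d$sample[[1]],
                  d[c("locus", "allele", "size_bp", "height_rfu", "dye")],
                  reference = reference)
    })
  names(profiles) <- purrr::map_chr(profiles, "sample")
  attr(profiles, "rejected") <- rejected
  profiles
}

#' Row-level rejection report from [read_peak_table()]
#' @param profiles The list returned by [read_peak_table()].
#' @return Tibble with columns `row`, `sample`, `reason` (zero rows when all
#'   rows parsed).
#' @export
rejected_rows <- function(profiles) {
  attr(profiles, "rejected") %||%
    tibble::tibble(row = integer(), sample = character(),
                   reason = character())
}

#' Write profiles back out as a GeneMapper-style peak table
#'
#' Inverse of [read_peak_table()]: heights and sizes are written with full
#' double precision so a write/read round trip preserves the peak multiset
#' exactly.
#'
#' @param profiles A single [str_profile()] or a list of them.
#' @param file Output path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return `file`, invisibly.
#' @export
write_peak_table <- function(profiles, file, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  if (inherits(profiles, "str_profile")) profiles <- list(profiles)
  tab <- purrr::map(profiles, function(p) {
    dplyr::mutate(p$peaks, `Sample File` = p$sample, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select(`Sample File`, Dye = "dye", Marker = "locus",
                  Allele = "allele", Size = "size_bp", Height = "height_rfu")
  if (dialect == "tab") readr::write_tsv(tab, file)
  else readr::write_csv(tab, file)
  invisible(file)
}

#' Threshold-based allele calling
#'
#' Applies the analytic thresholds used in forensic STR interpretation:
#' every peak must reach the heterozygous threshold, and a locus left with
#' exactly one surviving peak is treated as a homozygous candidate and held
#' to the (higher) homozygous threshold. Comparison is inclusive: a peak at
#' exactly the threshold survives. Duplicate `(locus, allele)` rows are
#' collapsed to the highest peak so the called profile has at most one peak
#' per allele position. Calling is idempotent.
#'
#' @param profile An [str_profile()].
#' @param het_threshold_rfu Heterozygous calling threshold (default 50 RFU).
#' @param hom_threshold_rfu Homozygous calling threshold (default 150 RFU).
#' @return The profile with sub-threshold peaks removed.
#' @examples
#' p <- str_profile("s1", tibble::tibble(
#'   locus = c("D3S1358", "D3S1358", "TPOX"), allele = c("15", "17", "8"),
#'   size_bp = c(121, 129, 330), height_rfu = c(49, 200, 140)
#' ))
#' call_alleles(p)$peaks  # 49 < 50 removed; lone 140 < 150 removed
#' @export
call_alleles <- function(profile, het_threshold_rfu = 50,
                         hom_threshold_rfu = 150) {
  stopifnot(inherits(profile, "str_profile"),
            het_threshold_rfu > 0, hom_threshold_rfu > 0)
  called <- profile$peaks |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::slice_max(.data$height_rfu, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$height_rfu >= het_threshold_rfu) |>
    dplyr::group_by(.data$locus) |>
    dplyr::filter(dplyr::n() > 1L |
                    .data$height_rfu >= hom_threshold_rfu) |>
    dplyr::ungroup()
  profile$peaks <- called
  profile
}

#' Profile completeness relative to the donor reference
#'
#' Counts how many of the expected donor allele positions carry a called,
#' non-artefact peak, and derives the percent allele loss and the
#' informativeness flag (12 or more observed alleles, the national-database
#' upload rule).
#'
#' @param profile An [str_profile()] (usually after [call_alleles()]).
#' @param reference A [reference_genotype()]; defaults to the one stored in
#'   the profile.
#' @return One-row tibble: `sample`, `observed`, `expected`,
#'   `percent_loss` (= 100 * (expected - observed) / expected),
#'   `informative`.
#' @export
allele_stats <- function(profile, reference = profile$reference) {
  stopifnot(inherits(profile, "str_profile"))
  if (is.null(reference)) {
    abort("a reference genotype is required", class = "smartpcr_domain_error")
  }
  if (!inherits(reference, "reference_genotype")) {
    reference <- reference_genotype(reference)
  }
  expected <- expected_allele_count(reference)
  if (expected == 0) {
    abort("reference genotype has no expected allele positions",
          class = "smartpcr_domain_error")
  }
  donor_peaks <- dplyr::filter(profile$peaks, !.data$artefact)
  observed <- nrow(dplyr::semi_join(
    dplyr::distinct(donor_peaks, .data$locus, .data$allele),
    reference, by = c("locus", "allele")
  ))
  tibble::tibble(
    sample = profile$sample,
    observed = observed,
    expected = expected,
    percent_loss = 100 * (expected - observed) / expected,
    informative = observed >= 12L
  )
}

#' Plot an STR profile as peak heights by locus
#'
#' @param object An [str_profile()].
#' @param ... Unused.
#' @return A ggplot object: one bar per called peak, faceted by dye when dye
#'   information is present.
#' @export
autoplot.str_profile <- function(object, ...) {
  d <- object$peaks
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$size_bp,
                                       y = .data$height_rfu)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$size_bp, yend = 0,
                                       colour = .data$artefact)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$artefact), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey20",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "fragment size (bp)", y = "peak height (RFU)",
                  title = object$sample)
  if (!all(is.na(d$dye))) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$dye), ncol = 1)
  }
  p
}
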