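## Transcribed reference tables shipped with the package, with integrity
## checksums, and conversion of segment tables to SegmentSpec objects.

.FIXTURES <- c(
  media_basic             = "media_basic.csv",
  media_alternative       = "media_alternative.csv",
  small_phantoms          = "small_phantoms.csv",
  am_fractions_adult      = "am_fractions_adult.csv",
  density_differences     = "density_differences.csv",
  cortical_faces_example  = "cortical_faces_example.csv",
  segment_counts_adult    = "segment_counts_adult.csv",
  skeletal_df_adult       = "skeletal_df_adult.csv",
  uncertainty_budget      = "uncertainty_budget.csv",
  synthetic_segments_adult = "synthetic_segments_adult.csv")

# md5 sums of the repository copies; regenerated by scratch tooling when a
# table is retranscribed
.FIXTURE_MD5 <- c(
  media_basic             = "c93c02bc9a197b18539a4649a65e6a22",
  media_alternative       = "c630486ec281155857028d9257d50baf",
  small_phantoms          = "820ce7bd64ac1104a029d505e798b268",
  am_fractions_adult      = "d4d80a9bcb6783810bb54d42099c7080",
  density_differences     = "a81619bd3e41e3411541edce63990e24",
  cortical_faces_example  = "cce3ba5219334d5d7ef37bdbe713cb4d",
  segment_counts_adult    = "ddf88efb4c85ce171d39a6b5f5db5891",
  skeletal_df_adult       = "c5ce1574a06615e5470a9f181f7076cf",
  uncertainty_budget      = "07c40fcfbd1703e44be6b7fe0998f536",
  synthetic_segments_adult = "3d3d5cf006dd3aae5f1a7db002493cb0")

#' Load a bundled reference table
#'
#' Bundled tables: media compositions (`media_basic`,
#' `media_alternative`), the six small validation phantoms
#' (`small_phantoms`), adult active-marrow distribution
#' (`am_fractions_adult`), bone-density sensitivity results
#' (`density_differences`), the per-face cortical randomization example
#' (`cortical_faces_example`), adult site/segment counts
#' (`segment_counts_adult`), adult skeletal-average dose factors with
#' uncertainty split (`skeletal_df_adult`), the resolved uncertainty budget
#' (`uncertainty_budget`) and a synthetic 47-segment adult library
#' (`synthetic_segments_adult`; a constructed stand-in, not measured data).
#' Each file is checksummed against the repository copy at load.
#'
#' @param name fixture name.
#' @return data.frame.
#' @examples
#' loadFixture("media_basic")
#' @export
loadFixture <- function(name) {
  if (!name %in% names(.FIXTURES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.FIXTURES), collapse = ", "))
  path <- system.file("extdata", .FIXTURES[[name]], package = "spsdose",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!grepl("^@", .FIXTURE_MD5[[name]]) && md5 != .FIXTURE_MD5[[name]])
    stop("fixture '", name, "' fails its integrity checksum")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

parseDims <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
parseMask <- function(s) as.logical(as.integer(strsplit(s, ";", fixed = TRUE)[[1]]))

#' Convert a segment table row set to SegmentSpec objects
#'
#' Accepts the CSV layout of `synthetic_segments_adult` (one row per
#' segment; `dims` and `coverage` serialized as `;`-delimited lists).
#'
#' @param tab data.frame as returned by [loadFixture()] or
#'   [readSegmentTable()].
#' @return named list of [SegmentSpec-class] objects.
#' @export
segmentsFromTable <- function(tab) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    SegmentSpec(
      site_id = r$site, segment_id = r$segment_id,
      shape = ShapeSpec(r$shape, parseDims(r$dims)),
      ct_th = r$ct_th, cortical_coverage = parseMask(r$coverage),
      micro = MicroSpec(r$tb_th, r$tb_sp, r$bvtv,
                        tb_th_sd = r$tb_th_cv * r$tb_th,
                        tb_sp_sd = r$tb_sp_cv * r$tb_sp,
                        bvtv_range = c(r$bvtv_min, r$bvtv_max)),
      marrow_mass = r$marrow_mass,
      variability = VariabilityModel(macro_cv = r$macro_cv,
                                     ct_th_cv = r$ct_th_cv,
                                     tb_th_cv = r$tb_th_cv,
                                     tb_sp_cv = r$tb_sp_cv))
  })
  names(out) <- tab$segment_id
  out
}

#' Adult active-marrow distribution as an AMDistribution
#'
#' Uses the measured adult fractions and the overall assumed per-site CVs.
#'
#' @return an [AMDistribution-class].
#' @export
adultAMDistribution <- function() {
  tab <- loadFixture("am_fractions_adult")
  AMDistribution(tab$site, tab$campbell_fraction, tab$assumed_cv)
}
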