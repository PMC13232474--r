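#' Canonical marker genes for tumor-microenvironment populations
#'
#' CAF subtypes are assigned by single canonical markers: FN1 (myCAF),
#' C3 (iCAF), CD74 (apCAF), SLC14A1 (IFN-CAF) and PSCA (PSCA-CAF).
#' Macrophage polarization is scored with the M1 set (CD80, CD86, NOS2,
#' IL12B, IL1B, CXCL9, CXCL10, CXCL11, EMP1) and the M2 set (CD163, ARG1,
#' IL10, TGFB1, C1QA, C1QB, C1QC, MMP9).
#'
#' @return `caf_markers()` a named list mapping CAF subtype to marker
#'   gene(s); `m1_markers()` / `m2_markers()` character vectors.
#' @export
caf_markers <- function() {
  list(myCAF = "FN1", iCAF = "C3", apCAF = "CD74",
       "IFN-CAF" = "SLC14A1", "PSCA-CAF" = "PSCA")
}

#' @rdname caf_markers
#' @export
m1_markers <- function() {
  c("CD80", "CD86", "NOS2", "IL12B", "IL1B",
    "CXCL9", "CXCL10", "CXCL11", "EMP1")
}

#' @rdname caf_markers
#' @export
m2_markers <- function() {
  c("CD163", "ARG1", "IL10", "TGFB1", "C1QA", "C1QB", "C1QC", "MMP9")
}
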