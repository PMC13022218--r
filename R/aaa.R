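# package-wide constants
#' @importFrom rlang %||% .data
NULL

# nodata sentinel used when serialising ASCII grids
ASC_NODATA <- -9999

# NLCD-style aggregate land-use classes carried per wetland (percent cover)
LANDUSE_CLASSES <- c("OP", "DA", "BL", "FO", "SS", "HB", "HP", "CC", "WW", "EHW")

# canonical feature orderings, recorded on every feature table
DISCRETE_FEATURES <- c("Area", "Perimeter", "SCI", "PPS", "AveRain", "AveTemp",
                       LANDUSE_CLASSES)
S2_BANDS <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
CONTINUOUS_FEATURES <- c(S2_BANDS, "NDVI", "NDWI", "EVI",
                         "VV", "VH", "VV_VH", "VH_VV", "SRVI")
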