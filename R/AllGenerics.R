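#' @rdname EpireadSet-class
#' @export
setGeneric("epireads", function(x) standardGeneric("epireads"))

#' @rdname EpireadSet-class
#' @export
setGeneric("cohortDesign", function(x) standardGeneric("cohortDesign"))

#' @rdname EpireadSet-class
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname CpGMap-class
#' @export
setGeneric("cpgSites", function(x, chrom = NULL) standardGeneric("cpgSites"))

#' @rdname CpGMap-class
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname RegionSet-class
#' @export
setGeneric("coreRegions", function(x) standardGeneric("coreRegions"))

#' @rdname RegionSet-class
#' @export
setGeneric("flankedRegions", function(x) standardGeneric("flankedRegions"))

#' @rdname RegionSet-class
#' @export
setGeneric("flankSize", function(x) standardGeneric("flankSize"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("entropyPooled", function(x) standardGeneric("entropyPooled"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("entropyWithin", function(x) standardGeneric("entropyWithin"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("entropyBetween", function(x) standardGeneric("entropyBetween"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("windowIds", function(x) standardGeneric("windowIds"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
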