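#' @rdname dosageMatrix
#' @export
setGeneric("dosageMatrix", function(x, role, ...)
  standardGeneric("dosageMatrix"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname TrioCohort-accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
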