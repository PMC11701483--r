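#' @name BiotypeGraph-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param object an S4 object from this package.
#' @return the requested slot content (see the individual methods).
NULL

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("diagnosisLabels", function(object) standardGeneric("diagnosisLabels"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("patientMask", function(object) standardGeneric("patientMask"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("subjectTable", function(object) standardGeneric("subjectTable"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("embeddings", function(object) standardGeneric("embeddings"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("biotypes", function(object) standardGeneric("biotypes"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("componentCount", function(object) standardGeneric("componentCount"))

#' @rdname BiotypeGraph-generics
#' @export
setGeneric("networkSizes", function(object) standardGeneric("networkSizes"))
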