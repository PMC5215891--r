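#' @include AllClasses.R
NULL

#' Accessors for wormFAS objects
#'
#' \code{neuronNames} returns the ordered neuron identifiers of a
#' \linkS4class{Connectome}; \code{nNeurons} its size; \code{gapCounts}
#' and \code{synCounts} the count matrices; \code{polarity} the
#' excitatory/inhibitory labels; \code{neuronGroups} the named group
#' list; \code{neuronClasses} the per-neuron class labels.
#'
#' @param object a wormFAS object.
#' @return the requested component.
#' @name accessors
#' @aliases neuronNames nNeurons gapCounts synCounts polarity neuronGroups
#'   neuronClasses
NULL

#' @rdname accessors
#' @export
setGeneric("neuronNames", function(object) standardGeneric("neuronNames"))
#' @rdname accessors
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("gapCounts", function(object) standardGeneric("gapCounts"))
#' @rdname accessors
#' @export
setGeneric("synCounts", function(object) standardGeneric("synCounts"))
#' @rdname accessors
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))
#' @rdname accessors
#' @export
setGeneric("neuronGroups", function(object) standardGeneric("neuronGroups"))
#' @rdname accessors
#' @export
setGeneric("neuronClasses", function(object) standardGeneric("neuronClasses"))

#' @rdname accessors
setMethod("neuronNames", "Connectome", function(object) object@neuronNames)
#' @rdname accessors
setMethod("nNeurons", "Connectome", function(object) length(object@neuronNames))
#' @rdname accessors
setMethod("gapCounts", "Connectome", function(object) object@Ng)
#' @rdname accessors
setMethod("synCounts", "Connectome", function(object) object@Ns)
#' @rdname accessors
setMethod("polarity", "Connectome", function(object) object@polarity)
#' @rdname accessors
setMethod("neuronGroups", "Connectome", function(object) object@groups)
#' @rdname accessors
setMethod("neuronClasses", "Connectome", function(object) object@classes)

#' @rdname accessors
#' @export
setGeneric("swellings", function(object) standardGeneric("swellings"))
#' @rdname accessors
setMethod("swellings", "InjuryVector", function(object) object@m)

#' @rdname accessors
#' @export
setGeneric("injuryAmplitude", function(object) standardGeneric("injuryAmplitude"))
#' @rdname accessors
setMethod("injuryAmplitude", "InjuryVector", function(object) object@mu)

#' @rdname accessors
#' @export
setGeneric("planeModes", function(object) standardGeneric("planeModes"))
#' @rdname accessors
setMethod("planeModes", "NeuralPlane", function(object) object@modes)

#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @rdname accessors
setMethod("singularValues", "NeuralPlane", function(object) object@singularValues)

#' @rdname accessors
#' @export
setGeneric("shapePoints", function(object) standardGeneric("shapePoints"))
#' @rdname accessors
setMethod("shapePoints", "Shape", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("muStar", function(object) standardGeneric("muStar"))
#' @rdname accessors
setMethod("muStar", "MuProfile", function(object) object@muStar)
#' @rdname accessors
setMethod("muStar", "PDCurve", function(object) object@muStar)

#' @rdname accessors
#' @export
setGeneric("endpointLabels", function(object) standardGeneric("endpointLabels"))
#' @rdname accessors
setMethod("endpointLabels", "EndpointSet", function(object) object@labels)

setMethod("show", "Connectome", function(object) {
    cat("Connectome with", nNeurons(object), "neurons\n")
    cat("  gap junctions:", sum(object@Ng) / 2,
        " chemical synapses:", sum(object@Ns), "\n")
    cat("  polarity:", sum(object@polarity == "excitatory"), "excitatory /",
        sum(object@polarity == "inhibitory"), "inhibitory\n")
    if (length(object@groups))
        cat("  groups:", paste(sprintf("%s(%d)", names(object@groups),
            lengths(object@groups)), collapse = ", "), "\n")
})

setMethod("show", "ModelParams", function(object) {
    cat("ModelParams: C =", object@C, "pF, Gc =", object@Gc, "pS, Ecell =",
        object@Ecell, "mV, g =", object@g, "pS\n")
    cat("  Eexc =", object@Eexc, "mV, Einh =", object@Einh, "mV, beta =",
        object@beta, "/mV, ar =", object@ar, "/s, ad =", object@ad,
        "/s, dt =", object@dt, "s\n")
    cat("  Vth:", if (length(object@Vth)) sprintf("set (%d neurons)",
        length(object@Vth)) else "unset (use restingState)", "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", length(object@times), "samples x", ncol(object@V),
        "neurons, t in [", min(object@times), ",", max(object@times), "] s\n")
})

setMethod("show", "InjuryVector", function(object) {
    cat("InjuryVector over", length(object@m), "neurons; mu =",
        if (length(object@mu)) object@mu else NA,
        "; protected:", paste(object@protected, collapse = ", "), "\n")
})

setMethod("show", "NeuralPlane", function(object) {
    ef <- sum(object@singularValues[1:2]^2) / sum(object@singularValues^2)
    cat("NeuralPlane over", length(object@subset), "neurons;",
        sprintf("two-mode energy fraction %.4f\n", ef))
})

setMethod("show", "PlaneTrajectory", function(object) {
    cat("PlaneTrajectory:", length(object@times), "samples, t in [",
        min(object@times), ",", max(object@times), "] s\n")
})

setMethod("show", "Shape", function(object) {
    cat("Shape: closed curve with", ncol(object@points), "points\n")
})

setMethod("show", "MuProfile", function(object) {
    cat("MuProfile: muStar =", object@muStar, "with",
        length(object@muSamples), "mu samples\n")
})

setMethod("show", "PDCurve", function(object) {
    cat("PDCurve:", length(object@mu), "samples, muStar =", object@muStar,
        ", max PD =", if (length(object@pd)) max(object@pd, na.rm = TRUE) else NA, "\n")
})

setMethod("show", "EndpointSet", function(object) {
    tab <- table(object@labels)
    cat("EndpointSet:", nrow(object@endpoints), "endpoints;",
        paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
              collapse = ", "), "\n")
})

setMethod("show", "TreeModel", function(object) {
    cat("TreeModel:", sum(object@nodes$isLeaf), "leaves, minLeaf =",
        object@minLeaf, "\n  split features:",
        paste(unique(stats::na.omit(object@nodes$feature)), collapse = ", "), "\n")
})
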