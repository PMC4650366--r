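#' @rdname FrameStack-class
#' @param x,object an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname FrameStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ColonyTrackSet-class
#' @param x,object an object.
#' @export
setGeneric("trackInfo", function(x) standardGeneric("trackInfo"))

#' @rdname ColonyTrackSet-class
#' @param id a track id.
#' @export
setGeneric("trackHistory", function(x, id) standardGeneric("trackHistory"))

#' @rdname ColonyTrackSet-class
#' @export
setGeneric("fusionEvents", function(x) standardGeneric("fusionEvents"))

#' @rdname CountSeries-class
#' @param x,object an object.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname SteadyDecision-class
#' @param x,object an object.
#' @export
setGeneric("steadyFound", function(x) standardGeneric("steadyFound"))

#' @rdname SteadyDecision-class
#' @export
setGeneric("nStdy", function(x) standardGeneric("nStdy"))

#' @rdname SteadyDecision-class
#' @export
setGeneric("tStdy", function(x) standardGeneric("tStdy"))

#' @rdname SteadyDecision-class
#' @export
setGeneric("criterionUsed", function(x) standardGeneric("criterionUsed"))
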