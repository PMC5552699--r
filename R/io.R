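# Serialization: networks as schema-checked JSON documents, trajectories
# as full-precision CSV. All numbers are in the fixed unit convention
# (mV, nA, uS, nF, ms).

NETWORK_FORMAT <- "sns_network/1"

neuron_fields <- c("name", "Cm", "Gm", "Iapp_tonic")
synapse_fields <- c("pre", "post", "gs", "dEs", "R", "Elo")

check_fields <- function(obj, allowed, required, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop("unknown field(s) in ", where, ": ", paste(extra, collapse = ", "))
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("missing required field(s) in ", where, ": ",
         paste(missing, collapse = ", "))
}

#' Write / read a network as JSON
#'
#' Networks serialize to a versioned JSON document (`neurons`, `synapses`,
#' `inputs`, `metadata`). Reading validates the document: unknown fields
#' are rejected with their location, missing required fields are named, and
#' all construction invariants (positive `Cm`, non-negative `gs`, declared
#' endpoints, unique names) are re-checked. Write then read is lossless.
#'
#' @param net An `sns_network`.
#' @param path File path.
#' @return `read_network()` returns the `sns_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "sns_network"))
  doc <- list(
    format = NETWORK_FORMAT,
    neurons = lapply(unname(net$neurons), function(n) n[neuron_fields]),
    synapses = lapply(net$synapses, function(s) s[synapse_fields]),
    inputs = lapply(net$inputs, as.list),
    metadata = net$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_fields(doc, c("format", "neurons", "synapses", "inputs", "metadata"),
               c("format", "neurons"), "network document")
  if (!identical(doc$format, NETWORK_FORMAT))
    stop("unsupported network format version: '", doc$format,
         "' (expected '", NETWORK_FORMAT, "')")
  neurons <- lapply(doc$neurons, function(n) {
    check_fields(n, neuron_fields, c("name", "Cm"),
                 paste0("neuron '", if (!is.null(n$name)) n$name else "?", "'"))
    neuron_spec(n$name, Cm = n$Cm,
                Gm = if (is.null(n$Gm)) 1 else n$Gm,
                Iapp_tonic = if (is.null(n$Iapp_tonic)) 0 else n$Iapp_tonic)
  })
  synapses <- lapply(doc$synapses, function(s) {
    where <- paste0("synapse '", if (!is.null(s$pre)) s$pre else "?", " -> ",
                    if (!is.null(s$post)) s$post else "?", "'")
    check_fields(s, synapse_fields, c("pre", "post", "gs", "dEs", "R"), where)
    synapse_spec(s$pre, s$post, gs = s$gs, dEs = s$dEs, R = s$R,
                 Elo = if (is.null(s$Elo)) 0 else s$Elo)
  })
  inputs <- lapply(doc$inputs, function(p) unlist(p))
  network_spec(neurons, synapses, inputs,
               metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}

fmt_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

#' Write / read a simulation result as CSV
#'
#' Fixed column order: `time_ms`, then `U_<neuron>` for every neuron, then
#' `I_<port>` for every input port. Values are written with 17 significant
#' digits so a read-back reproduces the trajectory to machine precision.
#'
#' @param result An `sns_simulation`.
#' @param path File path.
#' @return `write_result()` returns `path` invisibly; `read_result()`
#'   returns a data frame with the columns above.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "sns_simulation"))
  header <- c("time_ms", paste0("U_", colnames(result$U)),
              if (ncol(result$I_ext)) paste0("I_", colnames(result$I_ext)))
  cols <- cbind(result$t, result$U, result$I_ext)
  lines <- c(paste(header, collapse = ","),
             if (nrow(cols)) apply(cols, 1, function(r)
               paste(fmt_full(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, check.names = FALSE)
}
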