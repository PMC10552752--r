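# Hash-chained fall-event ledger ----------------------------------------------
#
# A single-writer, append-only local embodiment of tamper-evident event
# storage: each block stores the SHA-256 digest of its predecessor, so any
# retroactive edit breaks the chain. Payloads are canonical JSON (sorted
# keys, no insignificant whitespace, UTF-8) so that serialization round-trips
# are hash-stable. Distributed consensus, encryption-at-rest and real
# messaging transports are out of scope; alert routing returns a plan object
# that a transport layer could act on.

GENESIS_HASH <- strrep("0", 64)

canonical_json <- function(x) {
  x <- x[order(names(x))]
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

block_hash <- function(index, timestamp, payload, prev_hash) {
  digest::digest(
    paste(index, timestamp, payload, prev_hash, sep = ""),
    algo = "sha256", serialize = FALSE
  )
}

#' Construct a fall event
#'
#' @param subject_id Opaque subject identifier.
#' @param predicted_class Predicted label in 0:2 (0 no fall, 1 slip /
#'   predicted fall, 2 actual fall).
#' @param confidence Classifier confidence in `[0, 1]`.
#' @param timestamp ISO-8601 UTC string; defaults to the current time.
#' @param location Free-text location stub.
#' @return A `fall_event` list.
#' @export
fall_event <- function(subject_id, predicted_class, confidence,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"),
                       location = "") {
  if (!predicted_class %in% 0:2) stopf("fall_event(): class must be 0, 1 or 2")
  if (confidence < 0 || confidence > 1) {
    stopf("fall_event(): confidence must be in [0, 1]")
  }
  structure(
    list(confidence = as.numeric(confidence), location = location,
         predicted_class = as.integer(predicted_class),
         subject_id = as.character(subject_id),
         timestamp = as.character(timestamp)),
    class = "fall_event"
  )
}

#' Create a new ledger chain
#'
#' Starts a chain with the genesis block (index 0, all-zero previous hash).
#'
#' @param timestamp Genesis timestamp (ISO-8601 UTC).
#' @return A `fall_ledger`: list of blocks, each with `index`, `timestamp`,
#'   `payload` (canonical JSON string), `prev_hash`, `hash`.
#' @export
ledger_new <- function(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC")) {
  payload <- as.character(canonical_json(list(genesis = TRUE)))
  genesis <- list(
    index = 0L, timestamp = as.character(timestamp), payload = payload,
    prev_hash = GENESIS_HASH,
    hash = block_hash(0L, timestamp, payload, GENESIS_HASH)
  )
  structure(list(genesis), class = "fall_ledger")
}

#' Append a fall event to the ledger
#'
#' Verifies the chain, then appends one block whose payload is the canonical
#' JSON of the event and whose `prev_hash` is the current head's hash.
#'
#' @param chain A `fall_ledger`.
#' @param event A [fall_event()].
#' @param timestamp Block timestamp; defaults to the event's.
#' @return The extended ledger (length grows by exactly 1).
#' @export
ledger_append <- function(chain, event, timestamp = event$timestamp) {
  v <- ledger_verify(chain)
  if (!v$ok) {
    stopf("ledger_append(): chain integrity violated at block %d",
          v$first_bad_index)
  }
  head_block <- chain[[length(chain)]]
  idx <- head_block$index + 1L
  payload <- as.character(canonical_json(unclass(event)))
  block <- list(
    index = idx, timestamp = as.character(timestamp), payload = payload,
    prev_hash = head_block$hash,
    hash = block_hash(idx, timestamp, payload, head_block$hash)
  )
  chain[[length(chain) + 1L]] <- block
  chain
}

#' Verify ledger integrity
#'
#' Recomputes every block's hash and checks every `prev_hash` link and index
#' increment. Pure: never mutates the chain.
#'
#' @param chain A `fall_ledger`.
#' @return List with `ok` (logical) and `first_bad_index` (`NA` when intact;
#'   otherwise the index of the first violating block).
#' @export
ledger_verify <- function(chain) {
  prev <- NULL
  for (b in chain) {
    expected <- block_hash(b$index, b$timestamp, b$payload, b$prev_hash)
    bad <- !identical(b$hash, expected) ||
      (is.null(prev) && (b$index != 0L || b$prev_hash != GENESIS_HASH)) ||
      (!is.null(prev) && (b$prev_hash != prev$hash || b$index != prev$index + 1L))
    if (bad) return(list(ok = FALSE, first_bad_index = b$index))
    prev <- b
  }
  list(ok = TRUE, first_bad_index = NA_integer_)
}

#' @export
print.fall_ledger <- function(x, ...) {
  v <- ledger_verify(x)
  cat(sprintf("<fall_ledger> %d block(s) incl. genesis, %s\n", length(x),
              if (v$ok) "verified" else
                sprintf("INTEGRITY VIOLATION at block %d", v$first_bad_index)))
  invisible(x)
}

#' Route an alert plan for a fall event
#'
#' Severity-based recipient routing: an actual fall (class 2) requests
#' emergency medical assistance first, then notifies family and neighbours;
#' a slip / predicted fall (class 1) notifies family and the caregiver; no
#' fall (class 0) alerts nobody.
#'
#' @param event A [fall_event()].
#' @return An `alert_plan`: list with `recipients` (ordered, duplicate-free)
#'   and `rationale`.
#' @export
route_alert <- function(event) {
  plan <- switch(as.character(event$predicted_class),
    "2" = list(recipients = c("emergency_medical", "family", "neighbours"),
               rationale = "actual fall (class 2): severe, immediate medical assistance requested"),
    "1" = list(recipients = c("family", "caregiver"),
               rationale = "slip/stumble or predicted fall (class 1): substantial but not immediately life-threatening"),
    "0" = list(recipients = character(0),
               rationale = "no fall detected (class 0): no alert")
  )
  structure(plan, class = "alert_plan")
}

#' Read / write a ledger as JSONL
#'
#' One block per line, canonical field order; round-trips are hash-stable.
#'
#' @param chain A `fall_ledger`.
#' @param path File path.
#' @return `ledger_write()` returns `path` invisibly; `ledger_read()` the
#'   chain.
#' @export
ledger_write <- function(chain, path) {
  lines <- vapply(chain, function(b) {
    as.character(jsonlite::toJSON(b, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname ledger_write
#' @export
ledger_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  chain <- lapply(lines, function(l) {
    b <- jsonlite::fromJSON(l)
    b$index <- as.integer(b$index)
    b
  })
  structure(chain, class = "fall_ledger")
}
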