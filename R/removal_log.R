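#' Removal log
#'
#' Ordered record of every ASV or sample removed by a filtering rule,
#' with the measured values that triggered the rule.  Replaying a log on
#' the input table reproduces the filtered table exactly.
#'
#' @param entity_id character, removed ASV or sample IDs.
#' @param entity_kind `"asv"` or `"sample"`.
#' @param rule_id character, the rule that fired.
#' @param detail character, measured values (human-readable).
#' @return data.frame of class `removal_log`.
#' @export
removal_log <- function(entity_id = character(), entity_kind = character(),
                        rule_id = character(), detail = character()) {
  stopifnot(all(entity_kind %in% c("asv", "sample")))
  log <- data.frame(entity_id = as.character(entity_id),
                    entity_kind = as.character(entity_kind),
                    rule_id = as.character(rule_id),
                    detail = as.character(detail),
                    stringsAsFactors = FALSE)
  class(log) <- c("removal_log", "data.frame")
  log
}

#' @rdname removal_log
#' @param ... removal_log objects to concatenate, in order.
#' @export
bind_removal_logs <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("removal_log", "data.frame")
  out
}

#' Replay a removal log on a table
#'
#' Drops, in order, every logged ASV column and sample row from `table`;
#' the result must equal the filtered table the log came from.
#'
#' @param table the unfiltered [asv_table()].
#' @param log a [removal_log()].
#' @return The filtered `asv_table`.
#' @export
replay_removals <- function(table, log) {
  drop_asv <- unique(log$entity_id[log$entity_kind == "asv"])
  drop_sample <- unique(log$entity_id[log$entity_kind == "sample"])
  keep_s <- setdiff(rownames(table), drop_sample)
  keep_a <- setdiff(colnames(table), drop_asv)
  subset_asv_table(table, samples = keep_s, asvs = keep_a)
}
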