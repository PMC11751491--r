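#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy left-to-right clustering of adjusted hits. Inputs must be sorted by
// (strand, ref, delta). The first delta of a group opens a cluster (anchor
// = delta0); every following hit with delta - anchor <= D joins it and adds a
// vote; the first hit beyond D opens the next cluster. Boundaries between
// strands/references always close the cluster.
// [[Rcpp::export]]
DataFrame cluster_hits_cpp(IntegerVector strand, IntegerVector ref,
                           IntegerVector delta, IntegerVector ref_pos,
                           IntegerVector read_pos, IntegerVector span,
                           double D) {
  int n = (int) delta.size();
  std::vector<int> o_strand, o_ref, o_anchor, o_last, o_votes,
                   o_ref_lo, o_ref_hi, o_read_lo, o_read_hi;
  int i = 0;
  while (i < n) {
    int st = strand[i], rf = ref[i];
    int anchor = delta[i], last = delta[i], votes = 0;
    int ref_lo = ref_pos[i], ref_hi = ref_pos[i] + span[i];
    int read_lo = read_pos[i], read_hi = read_pos[i] + span[i];
    while (i < n && strand[i] == st && ref[i] == rf &&
           (double) (delta[i] - anchor) <= D) {
      last = delta[i];
      ++votes;
      if (ref_pos[i] < ref_lo) ref_lo = ref_pos[i];
      if (ref_pos[i] + span[i] > ref_hi) ref_hi = ref_pos[i] + span[i];
      if (read_pos[i] < read_lo) read_lo = read_pos[i];
      if (read_pos[i] + span[i] > read_hi) read_hi = read_pos[i] + span[i];
      ++i;
    }
    o_strand.push_back(st); o_ref.push_back(rf);
    o_anchor.push_back(anchor); o_last.push_back(last); o_votes.push_back(votes);
    o_ref_lo.push_back(ref_lo); o_ref_hi.push_back(ref_hi);
    o_read_lo.push_back(read_lo); o_read_hi.push_back(read_hi);
  }
  return DataFrame::create(
    _["strand"] = wrap(o_strand), _["ref"] = wrap(o_ref),
    _["anchor"] = wrap(o_anchor), _["last"] = wrap(o_last),
    _["votes"] = wrap(o_votes),
    _["ref_lo"] = wrap(o_ref_lo), _["ref_hi"] = wrap(o_ref_hi),
    _["read_lo"] = wrap(o_read_lo), _["read_hi"] = wrap(o_read_hi));
}
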