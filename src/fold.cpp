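#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Reference secondary-structure backend: a Zuker-style minimum-energy
// dynamic program over a fixed per-pair energy table (GC -3, AU -2, GU -1
// kcal/mol) with explicit loop penalties inside the recursion:
//   hairpin loop: +3; bulge/interior loop: +2 plus +1 per unpaired base
//   (each side capped at MAX_LOOP_SIDE nt); multiloop: +3.
// Nested structures only, minimum hairpin loop of `min_loop` unpaired
// bases. Deterministic traceback (stack > hairpin > smallest interior loop
// > multiloop) so identical input gives identical dot-bracket output.

static const int INF = 1000000;
static const int MAX_LOOP_SIDE = 10;
static const int HAIRPIN_PEN = 3;
static const int INTERIOR_PEN = 2;
static const int MULTI_PEN = 3;

static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1;
  return INF;
}

// [[Rcpp::export]]
List fold_backend_cpp(std::string seq, int min_loop) {
  int n = (int) seq.size();
  std::string db(n, '.');
  IntegerVector partner(n, NA_INTEGER);
  if (n < min_loop + 2) {
    return List::create(_["structure"] = db, _["energy"] = 0,
                        _["partner"] = partner);
  }
  // V[i][j]: min energy of [i..j] given i pairs j; M[i][j]: min energy of
  // [i..j] containing at least one branch, inside a multiloop (0-based)
  std::vector< std::vector<int> > V(n, std::vector<int>(n, INF));
  std::vector< std::vector<int> > M(n, std::vector<int>(n, INF));

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pe = pair_energy(seq[i], seq[j]);
      if (pe < INF) {
        int best = HAIRPIN_PEN;  // hairpin closed by (i, j)
        // stack / bulge / interior
        for (int l1 = 0; l1 <= MAX_LOOP_SIDE; ++l1) {
          int p = i + 1 + l1;
          if (p >= j) break;
          for (int l2 = 0; l2 <= MAX_LOOP_SIDE; ++l2) {
            int q = j - 1 - l2;
            if (q <= p) break;
            if (V[p][q] >= INF) continue;
            int cost = (l1 + l2 == 0) ? 0 : INTERIOR_PEN + l1 + l2;
            int alt = V[p][q] + cost;
            if (alt < best) best = alt;
          }
        }
        // multiloop: at least two branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          if (M[i + 1][k] >= INF || M[k + 1][j - 1] >= INF) continue;
          int alt = M[i + 1][k] + M[k + 1][j - 1] + MULTI_PEN;
          if (alt < best) best = alt;
        }
        V[i][j] = pe + best;
      }
      // M recurrence
      int m = V[i][j];
      if (M[i + 1][j] < m && i + 1 <= j) m = M[i + 1][j];
      if (j - 1 >= i && M[i][j - 1] < m) m = M[i][j - 1];
      for (int k = i + 1; k < j; ++k) {
        if (M[i][k] >= INF || M[k + 1][j] >= INF) continue;
        int alt = M[i][k] + M[k + 1][j];
        if (alt < m) m = alt;
      }
      M[i][j] = m;
    }
  }

  // exterior loop
  std::vector<int> W(n + 1, 0);
  std::vector<int> Wi(n + 1, 0);  // chosen i for traceback (1-based, 0 = unpaired)
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1];
    Wi[j] = 0;
    for (int i = 1; i <= j; ++i) {
      if (V[i - 1][j - 1] >= INF) continue;
      int alt = W[i - 1] + V[i - 1][j - 1];
      if (alt < W[j]) { W[j] = alt; Wi[j] = i; }
    }
  }

  // traceback
  struct Item { int i, j; char m; };
  std::stack<Item> todo;
  {
    int j = n;
    while (j > 0) {
      if (Wi[j] == 0) { --j; continue; }
      int i = Wi[j];
      todo.push({i - 1, j - 1, 'V'});
      j = i - 1;
    }
  }
  while (!todo.empty()) {
    Item it = todo.top(); todo.pop();
    int i = it.i, j = it.j;
    if (it.m == 'V') {
      db[i] = '('; db[j] = ')';
      partner[i] = j + 1; partner[j] = i + 1;
      int pe = pair_energy(seq[i], seq[j]);
      int rest = V[i][j] - pe;
      if (rest == HAIRPIN_PEN) {
        // could still be a co-optimal helix; prefer structural moves first
      }
      bool done = false;
      // stack first, then interior loops by ascending size
      for (int tot = 0; tot <= 2 * MAX_LOOP_SIDE && !done; ++tot) {
        for (int l1 = 0; l1 <= tot && !done; ++l1) {
          int l2 = tot - l1;
          if (l1 > MAX_LOOP_SIDE || l2 > MAX_LOOP_SIDE) continue;
          int p = i + 1 + l1, q = j - 1 - l2;
          if (p >= q || V[p][q] >= INF) continue;
          int cost = (tot == 0) ? 0 : INTERIOR_PEN + tot;
          if (rest == V[p][q] + cost) {
            todo.push({p, q, 'V'});
            done = true;
          }
        }
      }
      if (!done && rest == HAIRPIN_PEN) done = true;  // hairpin
      if (!done) {
        for (int k = i + 1; k < j - 1 && !done; ++k) {
          if (M[i + 1][k] >= INF || M[k + 1][j - 1] >= INF) continue;
          if (rest == M[i + 1][k] + M[k + 1][j - 1] + MULTI_PEN) {
            todo.push({i + 1, k, 'M'});
            todo.push({k + 1, j - 1, 'M'});
            done = true;
          }
        }
      }
    } else {  // M
      int e = M[i][j];
      if (e >= INF) continue;
      if (e == V[i][j]) { todo.push({i, j, 'V'}); continue; }
      if (i + 1 <= j && e == M[i + 1][j]) { todo.push({i + 1, j, 'M'}); continue; }
      if (j - 1 >= i && e == M[i][j - 1]) { todo.push({i, j - 1, 'M'}); continue; }
      for (int k = i + 1; k < j; ++k) {
        if (M[i][k] >= INF || M[k + 1][j] >= INF) continue;
        if (e == M[i][k] + M[k + 1][j]) {
          todo.push({i, k, 'M'});
          todo.push({k + 1, j, 'M'});
          break;
        }
      }
    }
  }

  return List::create(_["structure"] = db, _["energy"] = W[n],
                      _["partner"] = partner);
}

// Best ungapped end-shifted Hamming match of each tag against a mature-miRNA
// database. Tags and matures must differ in length by at most `max_len_diff`;
// alignments slide the tag by -max_shift..max_shift relative to the mature
// 5' end and mismatches are counted over the overlap.
// Returns, per tag: index of best database entry (1-based, NA if none),
// mismatch count, offset used.
// [[Rcpp::export]]
List match_known_cpp(CharacterVector tags, CharacterVector db,
                     int max_mismatch, int max_len_diff, int max_shift) {
  int nt = tags.size(), nd = db.size();
  IntegerVector best_idx(nt, NA_INTEGER), best_mm(nt, NA_INTEGER),
      best_off(nt, NA_INTEGER);
  std::vector<std::string> dbs(nd);
  for (int d = 0; d < nd; ++d) dbs[d] = as<std::string>(db[d]);
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    int lt = (int) tag.size();
    int bmm = max_mismatch + 1, bidx = -1, boff = 0, bov = -1;
    for (int d = 0; d < nd; ++d) {
      const std::string &m = dbs[d];
      int lm = (int) m.size();
      if (std::abs(lt - lm) > max_len_diff) continue;
      for (int off = -max_shift; off <= max_shift; ++off) {
        // tag position p aligns to mature position p + off (0-based)
        int lo = std::max(0, -off);            // first tag pos in overlap
        int hi = std::min(lt, lm - off);       // one past last tag pos
        int ov = hi - lo;
        if (ov < std::min(lt, lm) - max_shift) continue;
        int mm = 0;
        for (int p = lo; p < hi && mm <= max_mismatch; ++p)
          if (tag[p] != m[p + off]) ++mm;
        if (mm <= max_mismatch && (mm < bmm || (mm == bmm && ov > bov))) {
          bmm = mm; bidx = d; boff = off; bov = ov;
        }
      }
    }
    if (bidx >= 0) {
      best_idx[t] = bidx + 1;
      best_mm[t] = bmm;
      best_off[t] = boff;
    }
  }
  return List::create(_["db_index"] = best_idx, _["mismatches"] = best_mm,
                      _["offset"] = best_off);
}

// Slide a miRNA across every window of a transcript and score plant-style
// target complementarity. miRNA position i (1-based from its 5' end) faces
// transcript position start + L - i (antiparallel). Penalties: mismatch 1,
// G:U wobble 0.5, match 0; positions core_start..core_end doubled. Scores
// are returned in half-units internally for exactness.
// [[Rcpp::export]]
List scan_target_cpp(std::string mirna, std::string transcript,
                     int core_start, int core_end, double cutoff) {
  int L = (int) mirna.size(), n = (int) transcript.size();
  std::vector<int> starts;
  std::vector<double> scores;
  int cut2 = (int) (2.0 * cutoff + 1e-9);
  for (int s = 0; s + L <= n; ++s) {
    int pen2 = 0; // score in half-units
    for (int i = 0; i < L && pen2 <= cut2; ++i) {
      char m = mirna[i];
      char t = transcript[s + L - 1 - i];
      int p;
      if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
          (m == 'G' && t == 'C') || (m == 'C' && t == 'G'))
        p = 0;
      else if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G'))
        p = 1; // 0.5 in half-units
      else
        p = 2;
      if (i + 1 >= core_start && i + 1 <= core_end) p *= 2;
      pen2 += p;
    }
    if (pen2 <= cut2) {
      starts.push_back(s + 1); // 1-based
      scores.push_back(pen2 / 2.0);
    }
  }
  return List::create(_["start"] = wrap(starts), _["score"] = wrap(scores));
}
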