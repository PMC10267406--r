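// DPLL SAT solver with unit propagation over two watched literals, used for
// fixed-point and cycle enumeration. Literals follow the DIMACS convention
// (signed 1-based variable indices). Branching picks the lowest-numbered
// unassigned variable, so callers that place the semantically primary
// variables first (network state bits) get gate variables by propagation.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

namespace {

inline int lit_index(int lit) {
  // literal -> slot in the watch table: v>0 -> 2(v-1), v<0 -> 2(v-1)+1
  int v = std::abs(lit) - 1;
  return 2 * v + (lit < 0 ? 1 : 0);
}

struct Solver {
  int nvars;
  std::vector<std::vector<int>> clauses;
  std::vector<std::vector<int>> watchers;  // falsified-literal slot -> clauses
  std::vector<int> units;                  // unit clauses, applied at restart
  std::vector<signed char> assign;         // -1 unassigned, 0 false, 1 true

  explicit Solver(int nv) : nvars(nv), watchers(2 * nv), assign(nv, -1) {}

  bool value_true(int lit) const {
    signed char a = assign[std::abs(lit) - 1];
    return a != -1 && (a == 1) == (lit > 0);
  }
  bool value_false(int lit) const {
    signed char a = assign[std::abs(lit) - 1];
    return a != -1 && (a == 1) != (lit > 0);
  }

  void add_clause(const std::vector<int>& cl) {
    if (cl.size() == 1) {
      units.push_back(cl[0]);
      clauses.push_back(cl);
      return;
    }
    int ci = static_cast<int>(clauses.size());
    clauses.push_back(cl);
    // watch the first two literals
    watchers[lit_index(cl[0])].push_back(ci);
    watchers[lit_index(cl[1])].push_back(ci);
  }

  void undo(const std::vector<int>& trail) {
    for (int v : trail) assign[v] = -1;
  }

  // Assign queued literals and propagate; extends `trail` with every
  // variable set. Returns false on conflict (trail NOT undone).
  bool propagate(std::vector<int>& queue, std::vector<int>& trail) {
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      int lit = queue[qi];
      int v = std::abs(lit) - 1;
      signed char val = lit > 0 ? 1 : 0;
      if (assign[v] != -1) {
        if (assign[v] != val) return false;
        continue;
      }
      assign[v] = val;
      trail.push_back(v);
      // clauses watching the literal that just became false
      int slot = lit_index(-lit);
      std::vector<int>& ws = watchers[slot];
      size_t keep = 0;
      for (size_t wi = 0; wi < ws.size(); ++wi) {
        int ci = ws[wi];
        std::vector<int>& cl = clauses[ci];
        // normalize: put the falsified watch at position 1
        if (cl[0] == -lit) std::swap(cl[0], cl[1]);
        // clause already satisfied through the other watch?
        if (value_true(cl[0])) {
          ws[keep++] = ci;
          continue;
        }
        // look for a replacement watch
        bool moved = false;
        for (size_t k = 2; k < cl.size(); ++k) {
          if (!value_false(cl[k])) {
            std::swap(cl[1], cl[k]);
            watchers[lit_index(cl[1])].push_back(ci);
            moved = true;
            break;
          }
        }
        if (moved) continue;            // watcher migrated; drop from here
        ws[keep++] = ci;                // stays watched here
        if (assign[std::abs(cl[0]) - 1] == -1) {
          queue.push_back(cl[0]);       // unit
        } else {
          // other watch false too: conflict; restore remaining watchers
          for (size_t rest = wi + 1; rest < ws.size(); ++rest)
            ws[keep++] = ws[rest];
          ws.resize(keep);
          return false;
        }
      }
      ws.resize(keep);
    }
    return true;
  }

  // Recursive search; on success the assignment is complete and stays in
  // place. On failure the trail is rolled back.
  bool solve(std::vector<int> queue) {
    std::vector<int> trail;
    if (!propagate(queue, trail)) {
      undo(trail);
      return false;
    }
    int v = -1;
    for (int i = 0; i < nvars; ++i)
      if (assign[i] == -1) { v = i; break; }
    if (v < 0) return true;
    std::vector<int> q1(1, v + 1);
    if (solve(q1)) return true;
    std::vector<int> q0(1, -(v + 1));
    if (solve(q0)) return true;
    undo(trail);
    return false;
  }

  bool solve_fresh() {
    std::fill(assign.begin(), assign.end(), -1);
    return solve(units);
  }
};

Solver make_solver(const List& clauses, int nvars) {
  Solver s(nvars);
  for (R_xlen_t i = 0; i < clauses.size(); ++i) {
    IntegerVector cl = clauses[i];
    s.add_clause(std::vector<int>(cl.begin(), cl.end()));
  }
  return s;
}

}  // namespace

// Enumerate all models projected onto `project` (1-based variable indices):
// solve, record the projection, block it, repeat. Returns a list of logical
// vectors, one per model.
// [[Rcpp::export]]
List dpll_enumerate_cpp(List clauses, int nvars, IntegerVector project,
                        double limit) {
  Solver s = make_solver(clauses, nvars);
  std::vector<LogicalVector> out;
  while (static_cast<double>(out.size()) < limit) {
    if (!s.solve_fresh()) break;
    LogicalVector proj(project.size());
    std::vector<int> block(project.size());
    for (R_xlen_t j = 0; j < project.size(); ++j) {
      int v = project[j];
      bool val = s.assign[v - 1] == 1;
      proj[j] = val;
      block[j] = val ? -v : v;
    }
    out.push_back(proj);
    s.add_clause(block);
  }
  return wrap(out);
}

// Single solve; returns the full assignment or NULL when unsatisfiable.
// [[Rcpp::export]]
SEXP dpll_solve_cpp(List clauses, int nvars) {
  Solver s = make_solver(clauses, nvars);
  if (!s.solve_fresh()) return R_NilValue;
  LogicalVector model(nvars);
  for (int i = 0; i < nvars; ++i) model[i] = s.assign[i] == 1;
  return model;
}
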