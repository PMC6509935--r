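// Exhaustive synchronous attractor enumeration over the full state space.
//
// Each node's rule is pre-compiled (in R) to a truth table over its input
// nodes.  A state is a bit-packed word (bit i = node i).  The engine builds
// the successor map over all assignments of the *free* (unclamped) nodes and
// finds the cycles of that functional graph with an iterative path-walking
// pass: every state is visited O(1) times amortised, so 2^25 states stay
// well inside a per-test time budget.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct NodeFun {
    std::vector<int> inputs;   // bit positions of regulators (full-state bits)
    std::vector<uint8_t> tt;   // truth table, index bit j = inputs[j]
};

inline uint32_t next_state(uint32_t full, const std::vector<NodeFun> &funs,
                           const std::vector<int> &clampVal) {
    uint32_t out = 0;
    const int n = (int)funs.size();
    for (int i = 0; i < n; ++i) {
        uint32_t v;
        if (clampVal[i] >= 0) {
            v = (uint32_t)clampVal[i];
        } else {
            const NodeFun &f = funs[i];
            size_t idx = 0;
            for (size_t j = 0; j < f.inputs.size(); ++j)
                idx |= ((full >> f.inputs[j]) & 1u) << j;
            v = f.tt[idx];
        }
        out |= v << i;
    }
    return out;
}

} // namespace

// [[Rcpp::export(name = ".bn_attractors")]]
List bn_attractors(int n, List inputIdx, List truthTables,
                   IntegerVector clamps, NumericVector startFixedOn,
                   Nullable<NumericVector> explicitStarts) {
    if (n < 1 || n > 30) stop("node count out of range");

    std::vector<NodeFun> funs((size_t)n);
    std::vector<int> clampVal((size_t)n);
    for (int i = 0; i < n; ++i) {
        clampVal[i] = clamps[i];
        IntegerVector ii = inputIdx[i];
        IntegerVector tt = truthTables[i];
        funs[i].inputs.assign(ii.begin(), ii.end());
        if ((size_t)tt.size() != ((size_t)1 << ii.size()))
            stop("truth table size mismatch for node %d", i + 1);
        funs[i].tt.assign(tt.begin(), tt.end());
    }

    // free-node positions and clamp mask
    std::vector<int> freePos;
    uint32_t clampMask1 = 0;
    for (int i = 0; i < n; ++i) {
        if (clampVal[i] < 0) freePos.push_back(i);
        else if (clampVal[i] == 1) clampMask1 |= 1u << i;
    }
    const int f = (int)freePos.size();
    if (f > 25) stop("state space too large for exhaustive enumeration (2^%d free states)", f);
    const uint64_t N = (uint64_t)1 << f;

    // scatter/gather between free-space index and full state
    auto to_full = [&](uint32_t j) -> uint32_t {
        uint32_t full = clampMask1;
        for (int b = 0; b < f; ++b)
            full |= ((j >> b) & 1u) << freePos[b];
        return full;
    };
    auto to_index = [&](uint32_t full) -> uint32_t {
        uint32_t j = 0;
        for (int b = 0; b < f; ++b)
            j |= ((full >> freePos[b]) & 1u) << b;
        return j;
    };

    // successor map over the free space
    std::vector<uint32_t> succ(N);
    for (uint64_t j = 0; j < N; ++j)
        succ[j] = to_index(next_state(to_full((uint32_t)j), funs, clampVal));

    // start states: explicit list, or all states whose full form has the
    // startFixedOn bits set (empty mask = the whole space)
    uint32_t pulseMask = 0;
    for (int i = 0; i < startFixedOn.size(); ++i)
        pulseMask |= 1u << (int)startFixedOn[i];
    std::vector<uint32_t> starts;
    if (explicitStarts.isNotNull()) {
        NumericVector es(explicitStarts);
        starts.reserve(es.size());
        for (double v : es) {
            uint32_t full = ((uint32_t)v | clampMask1);  // project onto clamps
            for (int i = 0; i < n; ++i)
                if (clampVal[i] == 0) full &= ~(1u << i);
            starts.push_back(to_index(full));
        }
    } else if (pulseMask == 0) {
        starts.resize(N);
        for (uint64_t j = 0; j < N; ++j) starts[j] = (uint32_t)j;
    } else {
        // enumerate free bits not forced on by the pulse
        std::vector<int> loosePos;
        uint32_t pulseIdxMask = 0;
        for (int b = 0; b < f; ++b) {
            if (pulseMask & (1u << freePos[b])) pulseIdxMask |= 1u << b;
            else loosePos.push_back(b);
        }
        // pulse bits on clamped-0 nodes would be contradictory
        for (int i = 0; i < n; ++i)
            if ((pulseMask >> i & 1u) && clampVal[i] == 0)
                stop("pulse node is clamped to 0");
        const uint64_t M = (uint64_t)1 << loosePos.size();
        starts.reserve(M);
        for (uint64_t m = 0; m < M; ++m) {
            uint32_t j = pulseIdxMask;
            for (size_t b = 0; b < loosePos.size(); ++b)
                j |= ((m >> b) & 1u) << loosePos[b];
            starts.push_back(j);
        }
    }

    // cycle detection on the functional graph
    std::vector<int32_t> attrOf(N, -1);
    std::vector<int32_t> mark(N, -1);
    std::vector<uint32_t> path;
    std::vector<std::vector<uint32_t>> cycles;
    int32_t walk = 0;
    for (uint32_t s0 : starts) {
        if (attrOf[s0] >= 0) continue;
        path.clear();
        uint32_t s = s0;
        while (attrOf[s] < 0 && mark[s] != walk) {
            mark[s] = walk;
            path.push_back(s);
            s = succ[s];
        }
        int32_t aid;
        if (attrOf[s] >= 0) {
            aid = attrOf[s];
        } else {
            // s lies on the current path: the cycle is the path suffix from s
            size_t pos = path.size();
            while (pos > 0 && path[pos - 1] != s) --pos;
            --pos;
            std::vector<uint32_t> cyc(path.begin() + pos, path.end());
            aid = (int32_t)cycles.size();
            cycles.push_back(std::move(cyc));
        }
        for (uint32_t st : path) attrOf[st] = aid;
        ++walk;
    }

    // basins partition the start space (each listed start counts once)
    std::vector<double> basin(cycles.size(), 0.0);
    for (uint32_t s0 : starts) basin[attrOf[s0]] += 1.0;

    List outCycles(cycles.size());
    for (size_t a = 0; a < cycles.size(); ++a) {
        NumericVector cv(cycles[a].size());
        for (size_t i = 0; i < cycles[a].size(); ++i)
            cv[i] = (double)to_full(cycles[a][i]);
        outCycles[a] = cv;
    }
    return List::create(_["cycles"] = outCycles,
                        _["basin"] = NumericVector(basin.begin(), basin.end()),
                        _["nStarts"] = (double)starts.size());
}

// Follow one trajectory to its attractor (used by the R-level simulate for
// long transients; cycle detection by per-walk marking over a sparse map
// would be overkill -- transients in these models are short, so we just
// record visited states).
// [[Rcpp::export(name = ".bn_trajectory")]]
List bn_trajectory(int n, List inputIdx, List truthTables,
                   IntegerVector clamps, double start, double maxSteps) {
    std::vector<NodeFun> funs((size_t)n);
    std::vector<int> clampVal((size_t)n);
    for (int i = 0; i < n; ++i) {
        clampVal[i] = clamps[i];
        IntegerVector ii = inputIdx[i];
        IntegerVector tt = truthTables[i];
        funs[i].inputs.assign(ii.begin(), ii.end());
        funs[i].tt.assign(tt.begin(), tt.end());
    }
    uint32_t s = (uint32_t)start;
    // project onto clamps
    for (int i = 0; i < n; ++i) {
        if (clampVal[i] == 1) s |= 1u << i;
        else if (clampVal[i] == 0) s &= ~(1u << i);
    }
    std::vector<uint32_t> seen;
    std::unordered_map<uint32_t, size_t> pos;
    seen.reserve(64);
    for (double step = 0; ; ++step) {
        auto it = pos.find(s);
        if (it != pos.end()) {
            size_t cstart = it->second;
            NumericVector transient(cstart), cycle(seen.size() - cstart);
            for (size_t i = 0; i < cstart; ++i) transient[i] = (double)seen[i];
            for (size_t i = cstart; i < seen.size(); ++i)
                cycle[i - cstart] = (double)seen[i];
            return List::create(_["transient"] = transient, _["cycle"] = cycle);
        }
        if (step > maxSteps)
            stop("step budget exhausted before reaching an attractor");
        pos[s] = seen.size();
        seen.push_back(s);
        s = next_state(s, funs, clampVal);
    }
}
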