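#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D topological thinning of a binary volume to a centerline skeleton.
//
// Border voxels are peeled in six directional subiterations per pass; a
// voxel may be deleted only if it is a simple point for (26,6) connectivity
// (foreground 26-connected, background 6-connected) and not a curve
// endpoint (<= 1 foreground 26-neighbour). Simple points are characterised
// locally on the 3x3x3 neighbourhood: exactly one 26-component of
// foreground among the 26 neighbours, and exactly one 6-component of
// background within the 18-neighbourhood that touches a face neighbour.
// Deletion within a subiteration is sequential in ascending linear index,
// re-testing each voxel against the current image, so the result is
// deterministic and connectivity is preserved exactly.

static const int DX[27] = {-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1};
static const int DY[27] = {-1,-1,-1,0,0,0,1,1,1,-1,-1,-1,0,0,0,1,1,1,-1,-1,-1,0,0,0,1,1,1};
static const int DZ[27] = {-1,-1,-1,-1,-1,-1,-1,-1,-1,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1};
// index of (dx,dy,dz) in the 27-cube
static inline int cubeIndex(int dx, int dy, int dz) {
    return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static int fgNeighbourCount(const bool n[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i)
        if (i != 13 && n[i]) ++c;
    return c;
}

// exactly one 26-connected foreground component among the 26 neighbours
static bool oneForegroundComponent(const bool n[27]) {
    bool fg[27], vis[27] = {false};
    for (int i = 0; i < 27; ++i) fg[i] = n[i];
    fg[13] = false;
    int comps = 0;
    int stack[27];
    for (int s = 0; s < 27; ++s) {
        if (!fg[s] || vis[s]) continue;
        if (++comps > 1) return false;
        int top = 0;
        stack[top++] = s;
        vis[s] = true;
        while (top > 0) {
            int cur = stack[--top];
            for (int j = 0; j < 27; ++j) {
                if (!fg[j] || vis[j]) continue;
                int ax = std::abs(DX[cur] - DX[j]);
                int ay = std::abs(DY[cur] - DY[j]);
                int az = std::abs(DZ[cur] - DZ[j]);
                if (ax <= 1 && ay <= 1 && az <= 1) {
                    vis[j] = true;
                    stack[top++] = j;
                }
            }
        }
    }
    return comps == 1;
}

// exactly one 6-connected background component within the 18-neighbourhood
// that contains a face neighbour of the centre
static bool oneBackgroundComponent(const bool n[27]) {
    bool bg[27], vis[27] = {false};
    for (int i = 0; i < 27; ++i) {
        int man = std::abs(DX[i]) + std::abs(DY[i]) + std::abs(DZ[i]);
        bg[i] = (i != 13) && man <= 2 && !n[i];
    }
    int comps = 0;
    int stack[27];
    for (int s = 0; s < 27; ++s) {
        if (!bg[s] || vis[s]) continue;
        bool touchesFace = false;
        int top = 0;
        stack[top++] = s;
        vis[s] = true;
        while (top > 0) {
            int cur = stack[--top];
            if (std::abs(DX[cur]) + std::abs(DY[cur]) + std::abs(DZ[cur]) == 1)
                touchesFace = true;
            for (int j = 0; j < 27; ++j) {
                if (!bg[j] || vis[j]) continue;
                int ax = std::abs(DX[cur] - DX[j]);
                int ay = std::abs(DY[cur] - DY[j]);
                int az = std::abs(DZ[cur] - DZ[j]);
                if (ax + ay + az == 1) {
                    vis[j] = true;
                    stack[top++] = j;
                }
            }
        }
        if (touchesFace && ++comps > 1) return false;
    }
    return comps == 1;
}

static inline bool isSimple(const bool n[27]) {
    return oneForegroundComponent(n) && oneBackgroundComponent(n);
}

// [[Rcpp::export(name = ".thinMask3D")]]
LogicalVector thinMask3D(LogicalVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    if ((R_xlen_t)nx * ny * nz != mask.size())
        stop("mask size does not match dims");
    const int px = nx + 2, py = ny + 2, pz = nz + 2;
    std::vector<unsigned char> img((size_t)px * py * pz, 0);
    std::vector<int> fgList;
    fgList.reserve(1024);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                if (mask[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]) {
                    int p = (x + 1) + px * ((y + 1) + py * (z + 1));
                    img[p] = 1;
                    fgList.push_back(p);
                }
            }
    const int off[6] = {-1, +1, -px, +px, -px * py, +px * py};
    auto gather = [&](int p, bool n[27]) {
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx)
                    n[k++] = img[p + dx + px * (dy + py * dz)] != 0;
    };
    bool n[27];
    bool changed = true;
    std::vector<int> cand;
    while (changed) {
        changed = false;
        for (int d = 0; d < 6; ++d) {
            cand.clear();
            for (size_t i = 0; i < fgList.size(); ++i) {
                int p = fgList[i];
                if (!img[p]) continue;
                if (img[p + off[d]]) continue;  // not a border voxel for d
                gather(p, n);
                if (fgNeighbourCount(n) <= 1) continue;  // endpoint
                if (isSimple(n)) cand.push_back(p);
            }
            std::sort(cand.begin(), cand.end());
            for (size_t i = 0; i < cand.size(); ++i) {
                int p = cand[i];
                gather(p, n);  // re-test against the current image
                if (fgNeighbourCount(n) <= 1) continue;
                if (!isSimple(n)) continue;
                img[p] = 0;
                changed = true;
            }
        }
        if (changed) {
            size_t w = 0;
            for (size_t i = 0; i < fgList.size(); ++i)
                if (img[fgList[i]]) fgList[w++] = fgList[i];
            fgList.resize(w);
        }
    }
    LogicalVector out(mask.size());
    for (size_t i = 0; i < fgList.size(); ++i) {
        int p = fgList[i];
        int z = p / (px * py);
        int rem = p - z * px * py;
        int y = rem / px;
        int x = rem - y * px;
        out[(x - 1) + (R_xlen_t)nx * ((y - 1) + (R_xlen_t)ny * (z - 1))] = true;
    }
    return out;
}
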