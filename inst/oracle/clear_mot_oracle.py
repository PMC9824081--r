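#!/usr/bin/env python
"""Independent CLEAR MOT event counter.

Reads MOT-Challenge text files (frame,id,x,y,w,h,conf,...) for ground
truth and predictions and accumulates FN / FP / IDSW / GT totals and
MOTA under the CLEAR convention: correspondences remembered from an
identity's last matched frame are kept while both parties are present
and still overlap at the IoU gate; remaining boxes are matched by a
minimum-cost assignment maximising total IoU over pairs at or above the
gate; an identity switch is counted when a ground-truth identity's
matched predicted ID differs from its last matched predicted ID.

Usage:
  python clear_mot_oracle.py --root DIR [--iou 0.5]
      DIR contains scenario subdirectories, each with gt.txt and pred.txt
  python clear_mot_oracle.py --gt gt.txt --pred pred.txt [--iou 0.5]

Writes a JSON object to stdout.

This script is an oracle for the package's test suite only; it shares no
code with the R implementation.
"""
import argparse
import json
import os
import sys

import numpy as np
from scipy.optimize import linear_sum_assignment


def read_mot(path):
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            if not line:
                continue
            parts = line.split(",")
            rows.append([float(parts[0]), float(parts[1]), float(parts[2]),
                         float(parts[3]), float(parts[4]), float(parts[5])])
    if not rows:
        return np.zeros((0, 6))
    return np.asarray(rows)


def iou_matrix(a, b):
    if len(a) == 0 or len(b) == 0:
        return np.zeros((len(a), len(b)))
    ax1, ay1 = a[:, 0], a[:, 1]
    ax2, ay2 = a[:, 0] + a[:, 2], a[:, 1] + a[:, 3]
    bx1, by1 = b[:, 0], b[:, 1]
    bx2, by2 = b[:, 0] + b[:, 2], b[:, 1] + b[:, 3]
    ix = np.minimum(ax2[:, None], bx2[None, :]) - np.maximum(ax1[:, None],
                                                             bx1[None, :])
    iy = np.minimum(ay2[:, None], by2[None, :]) - np.maximum(ay1[:, None],
                                                             by1[None, :])
    inter = np.clip(ix, 0, None) * np.clip(iy, 0, None)
    area_a = (a[:, 2] * a[:, 3])[:, None]
    area_b = (b[:, 2] * b[:, 3])[None, :]
    return inter / (area_a + area_b - inter)


def accumulate(gt, pred, iou_thr):
    frames = sorted(set(gt[:, 0]).union(pred[:, 0]))
    last_match = {}
    fn = fp = idsw = gt_total = 0
    for t in frames:
        g = gt[gt[:, 0] == t]
        p = pred[pred[:, 0] == t]
        iou = iou_matrix(g[:, 2:6], p[:, 2:6])
        ng, np_ = len(g), len(p)
        gt_total += ng
        matched_g, matched_p = [], []
        # persistence of last-known pairings
        for i in range(ng):
            pid = last_match.get(g[i, 1])
            if pid is None:
                continue
            js = np.where(p[:, 1] == pid)[0]
            if len(js) and js[0] not in matched_p and iou[i, js[0]] >= iou_thr:
                matched_g.append(i)
                matched_p.append(int(js[0]))
        free_g = [i for i in range(ng) if i not in matched_g]
        free_p = [j for j in range(np_) if j not in matched_p]
        if free_g and free_p:
            sub = iou[np.ix_(free_g, free_p)]
            feas = sub >= iou_thr
            if feas.any():
                cost = -sub.copy()
                big = np.abs(cost[feas]).sum() + np.abs(cost[feas]).max() + 1
                cost[~feas] = big
                ri, ci = linear_sum_assignment(cost)
                for r, c in zip(ri, ci):
                    if feas[r, c]:
                        matched_g.append(free_g[r])
                        matched_p.append(free_p[c])
        for i, j in zip(matched_g, matched_p):
            gid, pid = g[i, 1], p[j, 1]
            prev = last_match.get(gid)
            if prev is not None and prev != pid:
                idsw += 1
            last_match[gid] = pid
        fn += ng - len(matched_g)
        fp += np_ - len(matched_p)
    mota = 1.0 - (fn + fp + idsw) / gt_total if gt_total else float("nan")
    return {"GT": gt_total, "FN": fn, "FP": fp, "IDSW": idsw, "MOTA": mota}


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--root")
    ap.add_argument("--gt")
    ap.add_argument("--pred")
    ap.add_argument("--iou", type=float, default=0.5)
    args = ap.parse_args()
    if args.root:
        out = {}
        for name in sorted(os.listdir(args.root)):
            d = os.path.join(args.root, name)
            if not os.path.isdir(d):
                continue
            out[name] = accumulate(read_mot(os.path.join(d, "gt.txt")),
                                   read_mot(os.path.join(d, "pred.txt")),
                                   args.iou)
        json.dump(out, sys.stdout)
    else:
        json.dump(accumulate(read_mot(args.gt), read_mot(args.pred),
                             args.iou), sys.stdout)


if __name__ == "__main__":
    main()
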