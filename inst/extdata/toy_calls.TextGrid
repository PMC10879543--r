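File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0
xmax = 30
tiers? <exists>
size = 2
item []:
    item [1]:
        class = "IntervalTier"
        name = "infant"
        xmin = 0
        xmax = 30
        intervals: size = 4
        intervals [1]:
            xmin = 0
            xmax = 12
            text = ""
        intervals [2]:
            xmin = 12
            xmax = 12.6
            text = "phee"
        intervals [3]:
            xmin = 12.6
            xmax = 20
            text = ""
        intervals [4]:
            xmin = 20
            xmax = 20.8
            text = "nga"
    item [2]:
        class = "IntervalTier"
        name = "caregiver"
        xmin = 0
        xmax = 30
        intervals: size = 2
        intervals [1]:
            xmin = 0
            xmax = 25
            text = ""
        intervals [2]:
            xmin = 25
            xmax = 25.9
            text = "twitter"
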