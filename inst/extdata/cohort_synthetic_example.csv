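subject_id,age,bmi,waist,smoking,secondhand_smoke,multivitamin,physical_activity,high_blood_pressure,diabetes,cholesterol,family_history,fish,fruits_vegetables,whole_grains,nuts,saturated_fat,trans_fat,unsaturated_fat,alcohol,chd_10yr
1,60,,le35in,never,regular,lt5wk,lt3hwk,yes,no,160to199,yes,lt2wk,lt5day,lt3day,ge3wk,lt2day,lt5wk,lt5wk,none,0
2,67,,le35in,quit_10to20y,rare,lt5wk,lt3hwk,no,no,160to199,no,lt2wk,lt5day,lt3day,lt3wk,lt2day,ge5wk,lt5wk,none,0
3,57,ge29,,never,rare,ge5wk,ge3hwk,no,no,240to299,no,ge2wk,ge5day,lt3day,lt3wk,lt2day,ge5wk,lt5wk,none,0
4,56,ge29,,quit_10to20y,regular,lt5wk,lt3hwk,no,no,le159,no,lt2wk,lt5day,lt3day,lt3wk,lt2day,lt5wk,ge5wk,none,0
5,47,lt25,,quit_lt2y,rare,ge5wk,ge3hwk,no,no,200to239,yes,lt2wk,lt5day,lt3day,lt3wk,ge2day,lt5wk,lt5wk,none,1
6,49,lt25,,current_15to24,,ge5wk,lt3hwk,yes,no,160to199,yes,lt2wk,ge5day,lt3day,lt3wk,lt2day,ge5wk,lt5wk,none,0
7,73,,gt35in,quit_ge20y,rare,lt5wk,ge3hwk,no,no,240to299,no,lt2wk,ge5day,lt3day,lt3wk,ge2day,lt5wk,lt5wk,ge1day,0
8,63,,le35in,quit_ge20y,rare,ge5wk,lt3hwk,no,no,240to299,no,lt2wk,ge5day,lt3day,ge3wk,lt2day,ge5wk,ge5wk,none,0
9,48,ge29,,quit_ge20y,rare,lt5wk,lt3hwk,no,no,240to299,no,ge2wk,ge5day,lt3day,lt3wk,lt2day,lt5wk,ge5wk,none,0
10,56,25to29,,never,rare,lt5wk,lt3hwk,yes,no,200to239,no,ge2wk,ge5day,lt3day,lt3wk,lt2day,ge5wk,ge5wk,none,0
11,74,,gt35in,never,rare,ge5wk,lt3hwk,no,no,200to239,no,lt2wk,ge5day,lt3day,lt3wk,ge2day,lt5wk,lt5wk,ge1day,0
12,50,lt25,,current_ge25,,ge5wk,ge3hwk,yes,no,le159,yes,lt2wk,ge5day,lt3day,ge3wk,lt2day,ge5wk,ge5wk,none,0
13,65,,gt35in,quit_2to10y,regular,lt5wk,ge3hwk,no,no,200to239,yes,lt2wk,ge5day,lt3day,lt3wk,ge2day,ge5wk,ge5wk,none,0
14,59,lt25,,never,regular,lt5wk,lt3hwk,no,no,200to239,no,lt2wk,lt5day,lt3day,lt3wk,ge2day,ge5wk,lt5wk,none,0
15,47,lt25,,current_15to24,,ge5wk,lt3hwk,no,no,200to239,no,lt2wk,lt5day,lt3day,lt3wk,lt2day,ge5wk,lt5wk,none,0
16,48,ge29,,current_15to24,,lt5wk,ge3hwk,yes,no,200to239,no,ge2wk,ge5day,lt3day,lt3wk,lt2day,ge5wk,ge5wk,none,0
17,52,lt25,,never,regular,ge5wk,lt3hwk,no,no,160to199,yes,lt2wk,ge5day,ge3day,lt3wk,lt2day,lt5wk,ge5wk,ge1day,0
18,49,ge29,,never,rare,ge5wk,lt3hwk,no,no,200to239,yes,lt2wk,ge5day,lt3day,lt3wk,lt2day,ge5wk,ge5wk,ge1day,0
19,58,lt25,,never,regular,lt5wk,ge3hwk,no,no,240to299,no,lt2wk,lt5day,lt3day,lt3wk,lt2day,ge5wk,lt5wk,none,0
20,57,ge29,,quit_2to10y,rare,lt5wk,lt3hwk,no,no,160to199,yes,lt2wk,ge5day,lt3day,lt3wk,ge2day,ge5wk,lt5wk,none,0
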